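#' Latent diffuse attenuation per waveband implied by water chemistry
#'
#' Applies the linear bio-optical model
#' `Kd(band) = kw + s_cdom * aCDOM340 + s_trip * tripton`
#' with the coefficients of `config$optics`.
#'
#' @param concentrations Tibble from [mix_downstream()].
#' @param config A [river_config()].
#' @return Tibble `station`, `band`, `kd` (m^-1).
#' @export
latent_kd <- function(concentrations, config) {
  tidyr::expand_grid(station = concentrations$station,
                     band = config$optics$band) %>%
    left_join(concentrations, by = "station") %>%
    left_join(config$optics, by = "band") %>%
    mutate(kd = .data$kw + .data$s_cdom * .data$acdom +
             .data$s_trip * .data$tripton) %>%
    select("station", "band", "kd")
}

# map each wavelength to the kd of the nearest configured band
wavelength_band_kd <- function(wavelengths, kd_by_band, bands) {
  dist_to <- function(a, b) pmax(a - wavelengths, wavelengths - b, 0)
  d <- vapply(seq_len(nrow(bands)),
              function(i) dist_to(bands$a[i], bands$b[i]),
              numeric(length(wavelengths)))
  nearest <- bands$name[max.col(-d, ties.method = "first")]
  unname(kd_by_band[nearest])
}

#' Generate hyperspectral downwelling irradiance depth profiles
#'
#' Inverts the attenuation measurement model: for each station,
#' `Ed(lambda, z) = Ed0(lambda) * exp(-Kd(lambda) * z)`, with the band Kd
#' from [latent_kd()] broadcast to each band's wavelengths (wavelengths
#' falling between bands take the nearest band's Kd), multiplicative
#' lognormal noise of standard deviation `config$profile_noise_sd` on the
#' log scale, depths on a `config$depth_step` grid (default 0.02 m) and
#' wavelengths 351-750 nm at 3 nm.
#'
#' Draws come from the current RNG stream; [simulate_river()] seeds it once
#' from `config$seed`.
#'
#' @param concentrations Tibble from [mix_downstream()].
#' @param config A [river_config()].
#' @param stations Optional subset of station ids.
#' @return Long tibble `station`, `depth_m`, `wavelength_nm`, `ed`
#'   (uW cm^-2 nm^-1).
#' @export
generate_profiles <- function(concentrations, config, stations = NULL) {
  kd_tab <- latent_kd(concentrations, config)
  if (any(kd_tab$kd < 0))
    rl_abort("configuration yields negative Kd", "config_error")
  wl <- seq(351, 750, by = 3)
  depths <- seq(0, config$profile_max_depth, by = config$depth_step)
  bands <- default_wavebands() %>% filter(.data$name %in% config$optics$band)
  ed0 <- surface_spectrum(config$ed0, wl)
  ids <- stations %||% concentrations$station
  purrr::map_dfr(ids, function(s) {
    kd_by_band <- kd_tab %>% filter(.data$station == s)
    kd_wl <- wavelength_band_kd(wl, setNames(kd_by_band$kd, kd_by_band$band),
                                bands)
    # depths x wavelengths matrix of log-irradiance
    lned <- outer(-depths, kd_wl) +
      matrix(log(ed0), nrow = length(depths), ncol = length(wl), byrow = TRUE)
    if (config$profile_noise_sd > 0)
      lned <- lned + rnorm(length(lned), sd = config$profile_noise_sd)
    tibble(
      station = s,
      depth_m = rep(depths, times = length(wl)),
      wavelength_nm = rep(wl, each = length(depths)),
      ed = exp(as.vector(lned))
    )
  })
}

surface_spectrum <- function(ed0, wavelengths) {
  if (is.numeric(ed0) && length(ed0) == 1) {
    rep(ed0, length(wavelengths))
  } else {
    tab <- as_tibble(ed0)
    if (!all(c("wavelength_nm", "ed") %in% names(tab)))
      rl_abort("ed0 table needs wavelength_nm and ed columns", "config_error")
    stats::approx(tab$wavelength_nm, tab$ed, xout = wavelengths, rule = 2)$y
  }
}
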