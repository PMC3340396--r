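#' Standard wavebands
#'
#' Default spectral wavebands (nm): PAR 400-700, blue 435-500, green 520-565,
#' red 625-740.
#'
#' @return Tibble with columns `name`, `a` (lower bound), `b` (upper bound).
#' @export
default_wavebands <- function() {
  tibble(name = c("par", "blue", "green", "red"),
         a = c(400, 435, 520, 625),
         b = c(700, 500, 565, 740))
}

#' Single waveband constructor
#'
#' @param name Band name.
#' @param a,b Lower/upper wavelength bounds, nm, `a < b`.
#' @return One-row tibble.
#' @export
waveband <- function(name, a, b) {
  if (!(a < b)) rl_abort("waveband requires a < b", "config_error")
  tibble(name = name, a = a, b = b)
}

# trapezoid integral of Ed * lambda / (h c N_A) over [a, b] on the measured
# wavelength grid; Ed in uW cm^-2 nm^-1, lambda in nm -> mol photons m^-2 s^-1
quanta_integral <- function(wavelength_nm, ed, a, b) {
  keep <- wavelength_nm >= a & wavelength_nm <= b
  wl <- wavelength_nm[keep]
  if (length(wl) < 2) rl_abort("band covers fewer than two measured wavelengths",
                               "domain_error")
  # uW cm^-2 nm^-1 -> W m^-2 nm^-1 is a factor 1e-2; lambda nm -> m is 1e-9
  integrand <- ed[keep] * 1e-2 * (wl * 1e-9) / (.PLANCK * .LIGHTSPEED)
  sum(diff(wl) * (head(integrand, -1) + integrand[-1]) / 2) / .AVOGADRO
}

#' Quanta-integrated waveband irradiance
#'
#' Converts energy irradiance to photon flux and integrates over a waveband:
#' `integral_a^b Ed(lambda) * lambda / (h c) dlambda / N_A`, by the trapezoid
#' rule on the measured wavelength grid, with Ed converted to SI before
#' integration. Units: umol photons m^-2 s^-1.
#'
#' @param profile Long tibble with columns `depth_m`, `wavelength_nm`, `ed`
#'   (and optionally `station`).
#' @param band One-row waveband table ([waveband()]) or a name from
#'   [default_wavebands()].
#' @return Tibble with one row per (station,) depth: column `quanta`
#'   (umol photons m^-2 s^-1).
#' @export
#' @examples
#' prof <- tidyr::expand_grid(depth_m = 0, wavelength_nm = seq(351, 750, 3))
#' prof$ed <- 100
#' integrate_quanta(prof, "par")
integrate_quanta <- function(profile, band) {
  band <- resolve_band(band)
  rng <- range(profile$wavelength_nm)
  if (band$a < rng[1] - 3 || band$b > rng[2] + 3)
    rl_abort(sprintf("band [%g, %g] outside measured range [%g, %g]",
                     band$a, band$b, rng[1], rng[2]), "domain_error")
  if (any(profile$ed < 0))
    rl_abort("negative irradiance: dark-correct the profile first",
             "domain_error")
  grouping <- intersect(c("station", "depth_m"), names(profile))
  profile %>%
    group_by(across(all_of(grouping))) %>%
    summarise(quanta = 1e6 * quanta_integral(.data$wavelength_nm, .data$ed,
                                             .env$band$a, .env$band$b),
              .groups = "drop")
}

resolve_band <- function(band) {
  if (is.character(band)) {
    wb <- default_wavebands()
    hit <- wb[wb$name == band, , drop = FALSE]
    if (nrow(hit) != 1) rl_abort(paste("unknown band:", band), "domain_error")
    return(hit)
  }
  band <- as_tibble(band)
  if (nrow(band) != 1 || !all(c("a", "b") %in% names(band)))
    rl_abort("band must be a single row with bounds a and b", "domain_error")
  band
}

#' Fit the diffuse attenuation coefficient of a waveband
#'
#' Integrates the profile to band photon flux at each depth, then fits an
#' ordinary least-squares regression of the natural logarithm of the band
#' irradiance on depth; `Kd` is minus the slope. Depths with nonpositive
#' integrated irradiance are dropped and counted. A nonnegative slope is
#' flagged invalid rather than silently returned, and fewer than 3 usable
#' depths is an error.
#'
#' @inheritParams integrate_quanta
#' @return Tibble with one row per station: `band`, `kd` (m^-1), `r2`,
#'   `n_depths`, `n_dropped`, `valid`, and `z1pct` = 4.6/Kd (m, `NA` when
#'   invalid).
#' @export
fit_kd <- function(profile, band) {
  band <- resolve_band(band)
  q <- integrate_quanta(profile, band)
  if (!"station" %in% names(q)) q$station <- "station"
  q %>%
    group_by(.data$station) %>%
    summarise(fit_kd_one(.data$depth_m, .data$quanta), .groups = "drop") %>%
    mutate(band = band$name %||% NA_character_, .after = "station")
}

fit_kd_one <- function(depth, quanta) {
  usable <- quanta > 0
  n_used <- sum(usable)
  if (n_used < 3)
    rl_abort("fewer than 3 depths with positive band irradiance",
             "insufficient_data_error")
  z <- depth[usable]
  y <- log(quanta[usable])
  fit <- lm.fit(cbind(1, z), y)
  slope <- fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  kd <- -slope
  valid <- is.finite(kd) && kd > 0
  tibble(kd = unname(kd), r2 = r2, n_depths = n_used,
         n_dropped = sum(!usable), valid = valid,
         z1pct = if (valid) 4.6 / unname(kd) else NA_real_)
}

#' 1% light penetration depth
#'
#' Depth at which irradiance falls to 1% of the surface value, using the
#' field's constant 4.6 (~ -ln 0.01).
#'
#' @param kd Diffuse attenuation coefficient(s), m^-1, > 0.
#' @return Depth(s) in metres.
#' @export
#' @examples
#' penetration_depth_1pct(0.46) # 10 m
penetration_depth_1pct <- function(kd) {
  if (any(kd <= 0)) rl_abort("kd must be > 0", "domain_error")
  4.6 / kd
}

#' Photic-zone fraction of the water column
#'
#' Percentage of the water column lit above the 1% level:
#' `min(100, (4.6/Kd) / depth * 100)`, capped at 100 when the photic zone
#' reaches bottom.
#'
#' @param kd Diffuse attenuation, m^-1, > 0.
#' @param water_depth Water-column depth, m, > 0.
#' @return Percentage in (0, 100].
#' @export
#' @examples
#' photic_fraction(0.46, 20) # 50
photic_fraction <- function(kd, water_depth) {
  if (any(kd <= 0) || any(water_depth <= 0))
    rl_abort("kd and water_depth must be > 0", "domain_error")
  pmin(100, penetration_depth_1pct(kd) / water_depth * 100)
}

#' Underwater color ratios from band attenuation
#'
#' `blue_red = Kd(red)/Kd(blue)` (equivalently z1pct(blue)/z1pct(red)) and
#' analogously `green_red`; a ratio > 1 means the numerator color penetrates
#' deeper than red. Invalid Kd fits propagate as `NA` with `valid = FALSE`.
#'
#' @param att_blue,att_green,att_red Per-station attenuation tibbles from
#'   [fit_kd()] (or any tibble with `station`, `kd`, `valid`).
#' @return Tibble `station`, `blue_red`, `green_red`, `valid`.
#' @export
color_ratio <- function(att_blue, att_green, att_red) {
  pick <- function(x, nm) {
    x <- as_tibble(x)
    if (!"station" %in% names(x)) x$station <- "station"
    if (!"valid" %in% names(x)) x$valid <- is.finite(x$kd) & x$kd > 0
    x %>% select("station", "kd", "valid") %>%
      rename_with(~ paste0(.x, "_", nm), c("kd", "valid"))
  }
  pick(att_blue, "blue") %>%
    left_join(pick(att_green, "green"), by = "station") %>%
    left_join(pick(att_red, "red"), by = "station") %>%
    mutate(valid = .data$valid_blue & .data$valid_green & .data$valid_red,
           blue_red = ifelse(.data$valid, .data$kd_red / .data$kd_blue, NA_real_),
           green_red = ifelse(.data$valid, .data$kd_red / .data$kd_green, NA_real_)) %>%
    select("station", "blue_red", "green_red", "valid")
}

#' CDOM absorption coefficient from absorbance
#'
#' Converts spectrophotometric absorbance at 340 nm to a Napierian absorption
#' coefficient, after subtracting the 690 nm baseline (where temperature
#' dependence is near zero): `aCDOM340 = 2.303 * (A340 - A690) / path_length`.
#'
#' @param a340 Absorbance at 340 nm.
#' @param a690 Baseline absorbance at 690 nm (default 0).
#' @param path_length Cuvette path length in metres (default 0.01 = 10 mm cell).
#' @return Absorption coefficient, m^-1.
#' @export
#' @examples
#' acdom_from_absorbance(0.1) # 23.03
acdom_from_absorbance <- function(a340, a690 = 0, path_length = 0.01) {
  if (any(path_length <= 0)) rl_abort("path_length must be > 0", "domain_error")
  2.303 * (a340 - a690) / path_length
}

#' Per-station optics table from spectral profiles
#'
#' Runs [fit_kd()] for every requested band, derives color ratios, the 1%
#' penetration depth of PAR, and (when station depths are supplied) the
#' photic-zone fraction.
#'
#' @param profiles Long profile tibble (`station`, `depth_m`,
#'   `wavelength_nm`, `ed`).
#' @param bands Waveband table, default [default_wavebands()].
#' @param station_depths Optional tibble `station`, `water_depth_m`.
#' @return Tibble, one row per station: `kd_<band>`, `r2_<band>`,
#'   `z1pct_<band>`, `blue_red`, `green_red`, and `photic_pct` if depths given.
#' @export
station_optics <- function(profiles, bands = default_wavebands(),
                           station_depths = NULL) {
  fits <- purrr::map_dfr(seq_len(nrow(bands)),
                         function(i) fit_kd(profiles, bands[i, ]))
  wide <- fits %>%
    select("station", "band", "kd", "r2", "z1pct") %>%
    tidyr::pivot_wider(names_from = "band",
                       values_from = c("kd", "r2", "z1pct"))
  if (all(c("blue", "green", "red") %in% bands$name)) {
    cr <- color_ratio(fits %>% filter(.data$band == "blue"),
                      fits %>% filter(.data$band == "green"),
                      fits %>% filter(.data$band == "red"))
    wide <- wide %>% left_join(cr %>% select(-"valid"), by = "station")
  }
  if (!is.null(station_depths) && "kd_par" %in% names(wide)) {
    wide <- wide %>%
      left_join(as_tibble(station_depths), by = "station") %>%
      mutate(photic_pct = photic_fraction(.data$kd_par, .data$water_depth_m))
  }
  wide
}
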