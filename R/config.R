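#' Configuration for a synthetic river
#'
#' Assembles and validates the full parameter set for the synthetic river
#' generator: network geometry (transects crossed by parallel lateral water
#' masses, called lanes), tributary endmembers, optical coefficients per
#' waveband, and the phytoplankton community response.
#'
#' The defaults emulate a large temperate river sampled over ~16 transects
#' with three lateral water masses (north / central / south) and a handful of
#' CDOM-, tripton- and nutrient-rich tributaries joining a clear main stem.
#'
#' @param n_transects Number of cross-river transects (downstream order).
#' @param stations_per_transect Stations per transect, one per lateral water
#'   mass ("lane"); lanes run parallel downstream.
#' @param tributaries Tibble with one row per tributary: `name`, `transect`,
#'   `lane` (attachment station), `discharge` (m^3 s^-1), and endmember
#'   concentrations `acdom` (m^-1 at 340 nm), `tripton` (mg L^-1),
#'   `srp` (ug L^-1). `NULL` for none.
#' @param main_discharge Main-stem discharge, m^3 s^-1 (split evenly over lanes).
#' @param main_endmember Named list/vector: `acdom`, `tripton`, `srp` of the
#'   head-of-river water.
#' @param optics Tibble with one row per waveband (`band`, `kw` baseline
#'   attenuation m^-1, `s_cdom` m^-1 per m^-1 of aCDOM340, `s_trip` m^-1 per
#'   mg L^-1 tripton). CDOM must absorb blue more strongly than red.
#' @param community Named list: `beta0`, `beta_color` (on ln blue/red),
#'   `beta_srp` (on ln SRP), `noise_sd`, and `rho` (AR(1) residual
#'   autocorrelation propagated along graph edges, 0 = white noise).
#' @param transect_spacing_km Downstream distance between transects.
#' @param ed0 Surface irradiance: a single value (flat spectrum,
#'   uW cm^-2 nm^-1) or a two-column table (`wavelength_nm`, `ed`).
#' @param profile_noise_sd SD of multiplicative lognormal noise on irradiance.
#' @param depth_step Depth grid step for light profiles, m.
#' @param profile_max_depth Maximum profiled depth, m.
#' @param depth_range Range (m) of station water-column depths, drawn uniformly.
#' @param srp_local_sd SD (log scale) of station-level lognormal variability
#'   applied to the mixed SRP field: phosphorus is strongly non-conservative
#'   (point sources, uptake, regeneration), so observed SRP departs from
#'   conservative mixing. 0 disables.
#' @param decay First-order decay rate per edge for dissolved constituents
#'   (0 = conservative mixing).
#' @param seed Integer seed; every stochastic draw flows from it.
#'
#' @return A validated list of class `river_config`.
#' @export
#' @examples
#' cfg <- river_config(n_transects = 4, stations_per_transect = 2, seed = 1)
#' cfg$n_transects
river_config <- function(n_transects = 16,
                         stations_per_transect = 3,
                         tributaries = default_tributaries(),
                         main_discharge = 7500,
                         main_endmember = list(acdom = 1.5, tripton = 1, srp = 6),
                         optics = default_optics(),
                         community = list(beta0 = 0.5, beta_color = 1.2,
                                          beta_srp = -0.6, noise_sd = 0.35,
                                          rho = 0),
                         transect_spacing_km = 28,
                         ed0 = 100,
                         profile_noise_sd = 0.05,
                         depth_step = 0.02,
                         profile_max_depth = 3,
                         depth_range = c(2, 12),
                         srp_local_sd = 0.5,
                         decay = 0,
                         seed = 1L) {
  cfg <- list(
    n_transects = as.integer(n_transects),
    stations_per_transect = as.integer(stations_per_transect),
    tributaries = if (is.null(tributaries)) NULL else as_tibble(tributaries),
    main_discharge = main_discharge,
    main_endmember = as.list(main_endmember),
    optics = as_tibble(optics),
    community = as.list(community),
    transect_spacing_km = transect_spacing_km,
    ed0 = ed0,
    profile_noise_sd = profile_noise_sd,
    depth_step = depth_step,
    profile_max_depth = profile_max_depth,
    depth_range = depth_range,
    srp_local_sd = srp_local_sd,
    decay = decay,
    seed = as.integer(seed)
  )
  class(cfg) <- "river_config"
  validate_river_config(cfg)
}

#' Default tributary set for the synthetic river
#'
#' Five tributaries with discharges and endmember chemistry on the scale of
#' the major inflows of a Great-Lakes-fed river (large CDOM-rich northern
#' inflow, smaller nutrient-rich southern ones).
#'
#' @return Tibble with columns `name`, `transect`, `lane`, `discharge`,
#'   `acdom`, `tripton`, `srp`.
#' @export
default_tributaries <- function() {
  tibble(
    name      = c("north_major", "north_small", "south_mid", "south_cdom", "north_mid"),
    transect  = c(4L, 7L, 9L, 10L, 12L),
    lane      = c(1L, 1L, 3L, 3L, 1L),
    discharge = c(1900, 60, 330, 190, 700),
    acdom     = c(25, 30, 12, 28, 22),
    tripton   = c(6, 8, 5, 7, 4),
    srp       = c(30, 40, 25, 35, 20)
  )
}

#' Default waveband attenuation coefficients
#'
#' Baseline (water + background) diffuse attenuation and the specific slopes
#' for CDOM and tripton per band. CDOM absorbs blue preferentially
#' (`s_cdom` decreasing from blue to red); tripton attenuation is nearly
#' spectrally flat.
#'
#' @return Tibble with columns `band`, `kw`, `s_cdom`, `s_trip`.
#' @export
default_optics <- function() {
  tibble(
    band   = c("blue", "green", "red"),
    kw     = c(0.06, 0.07, 0.40),
    s_cdom = c(0.16, 0.06, 0.012),
    s_trip = c(0.055, 0.050, 0.045)
  )
}

#' @rdname river_config
#' @param cfg A `river_config` object.
#' @export
validate_river_config <- function(cfg) {
  if (cfg$n_transects < 1L || cfg$stations_per_transect < 1L)
    rl_abort("n_transects and stations_per_transect must be >= 1", "config_error")
  if (cfg$main_discharge <= 0)
    rl_abort("main-stem discharge must be > 0", "config_error")
  em <- unlist(cfg$main_endmember[c("acdom", "tripton", "srp")])
  if (any(is.na(em)) || any(em < 0))
    rl_abort("main endmember concentrations must be >= 0", "config_error")
  tr <- cfg$tributaries
  if (!is.null(tr) && nrow(tr) > 0) {
    need <- c("name", "transect", "lane", "discharge", "acdom", "tripton", "srp")
    miss <- setdiff(need, names(tr))
    if (length(miss))
      rl_abort(paste("tributary table missing columns:",
                     paste(miss, collapse = ", ")), "config_error")
    if (any(tr$discharge <= 0))
      rl_abort("tributary discharges must be > 0", "config_error")
    if (any(tr$acdom < 0 | tr$tripton < 0 | tr$srp < 0))
      rl_abort("tributary endmember concentrations must be >= 0", "config_error")
    bad <- tr$transect < 1 | tr$transect > cfg$n_transects |
      tr$lane < 1 | tr$lane > cfg$stations_per_transect
    if (any(bad))
      rl_abort(paste("tributary attached to nonexistent station:",
                     paste(tr$name[bad], collapse = ", ")), "config_error")
  }
  op <- cfg$optics
  if (!all(c("band", "kw", "s_cdom", "s_trip") %in% names(op)))
    rl_abort("optics table must have band, kw, s_cdom, s_trip", "config_error")
  if (!all(c("blue", "red") %in% op$band))
    rl_abort("optics table must include blue and red bands", "config_error")
  if (op$s_cdom[op$band == "blue"] <= op$s_cdom[op$band == "red"])
    rl_abort("s_cdom(blue) must exceed s_cdom(red): CDOM absorbs blue preferentially",
             "config_error")
  if (any(op$kw < 0) || any(op$s_cdom < 0) || any(op$s_trip < 0))
    rl_abort("optical coefficients must be >= 0", "config_error")
  cm <- cfg$community
  if (is.null(cm$noise_sd) || cm$noise_sd < 0)
    rl_abort("community noise_sd must be >= 0", "config_error")
  rho <- cm$rho %||% 0
  if (abs(rho) >= 1)
    rl_abort("community rho must lie in (-1, 1)", "config_error")
  if (cfg$profile_noise_sd < 0 || cfg$depth_step <= 0 || cfg$profile_max_depth <= 0)
    rl_abort("profile parameters must be positive", "config_error")
  if ((cfg$srp_local_sd %||% 0) < 0)
    rl_abort("srp_local_sd must be >= 0", "config_error")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
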