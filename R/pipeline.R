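#' Configuration for a full riverscape analysis run
#'
#' Bundles the inputs (a simulation config, or paths to a station table CSV,
#' long-format profile CSV and edge-list TSV) with the analysis parameters of
#' every stage.
#'
#' @param simulation A [river_config()] (ignored when `inputs` given).
#' @param inputs Optional named list of paths: `stations`, `profiles`,
#'   `graph` (edge-list TSV).
#' @param response Station-table column to model (log-transformed when
#'   `response_log = TRUE`; the cyano/euk ratio is a ratio of counts, so the
#'   log scale is its natural home).
#' @param env Environmental predictor columns (taken from the fitted optics
#'   where available, otherwise from the station table).
#' @param response_log Model the response on the log scale?
#' @param alpha,n_permutations Forward-selection test parameters.
#' @param max_size Largest subset size in the best-subsets search.
#' @param vif_threshold Collinearity threshold for [vif_screen()].
#' @param adjusted Adjusted R-squared for the Venn fractions?
#' @param exclude_zones Stations whose `zone` is listed here are excluded
#'   from the AEM/partitioning stages (estuarine transition waters by
#'   default, whose tidal regime breaks the directional-flow assumption).
#' @param loess_span Span of the descriptive longitudinal smoother.
#' @param seed Seed for the selection permutations.
#' @return List of class `riverscape_config`.
#' @export
riverscape_config <- function(simulation = river_config(),
                              inputs = NULL,
                              response = "cyano_euk",
                              env = c("blue_red", "green_red", "kd_par", "srp",
                                      "temperature", "conductivity",
                                      "transmittance", "turbidity"),
                              response_log = TRUE,
                              alpha = 0.05,
                              n_permutations = 199,
                              max_size = 5,
                              vif_threshold = 5,
                              adjusted = TRUE,
                              exclude_zones = "ETZ",
                              loess_span = 0.5,
                              seed = 1L) {
  if (!is.null(inputs)) {
    missing_files <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing_files))
      rl_abort(paste("input files not found:",
                     paste(missing_files, collapse = ", ")), "config_error")
  }
  structure(list(simulation = simulation, inputs = inputs,
                 response = response, env = env, response_log = response_log,
                 alpha = alpha, n_permutations = n_permutations,
                 max_size = max_size, vif_threshold = vif_threshold,
                 adjusted = adjusted, exclude_zones = exclude_zones,
                 loess_span = loess_span, seed = as.integer(seed)),
            class = "riverscape_config")
}

#' Run the full riverscape analysis
#'
#' Executes the stages in order: simulate (or ingest) -> bio-optics from the
#' spectral profiles -> structural metrics of the bundled morphometry table
#' -> AEM spatial eigenfunctions and seeded forward selection -> VIF
#' screening and exhaustive best-subsets/AIC ranking of the environmental
#' predictors -> two-table variation partitioning and despatialized lmg
#' importance. When `outdir` is given, per-stage CSV/JSON files and a
#' provenance record (seed, config hash, package version) are written.
#'
#' @param config A [riverscape_config()].
#' @param outdir Optional output directory.
#' @param quiet Suppress per-stage messages?
#' @return List of class `riverscape_run` with elements `stations` (with
#'   fitted optics), `graph`, `optics`, `pdz`, `aem` (basis + selection),
#'   `screen`, `subsets`, `partition`, `importance`, `smooth`, `provenance`.
#' @export
run_riverscape <- function(config, outdir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "riverscape_config"))
  say <- function(stage, msg) if (!quiet) message("[", stage, "] ", msg)

  # --- ingest or simulate -------------------------------------------------
  if (is.null(config$inputs)) {
    sim <- simulate_river(config$simulation, profiles = TRUE)
    stations <- sim$stations
    profiles <- sim$profiles
    graph <- sim$graph
  } else {
    stations <- readr::read_csv(config$inputs$stations, show_col_types = FALSE)
    profiles <- readr::read_csv(config$inputs$profiles, show_col_types = FALSE)
    graph <- read_edge_list(config$inputs$graph)
    need <- c("station", config$response)
    miss <- setdiff(need, names(stations))
    if (length(miss))
      rl_abort(paste("station table missing columns:",
                     paste(miss, collapse = ", ")), "ingestion_error")
  }
  say("ingest", paste(nrow(stations), "stations"))
  no_profile <- setdiff(stations$station, unique(profiles$station))
  if (length(no_profile))
    rl_abort(paste("stations missing spectral profiles:",
                   paste(no_profile, collapse = ", ")), "ingestion_error")

  # --- bio-optics ---------------------------------------------------------
  depths <- if ("water_depth_m" %in% names(stations))
    stations[, c("station", "water_depth_m")] else NULL
  optics <- station_optics(profiles, station_depths = depths)
  say("optics", paste(nrow(optics), "stations fitted"))
  fitted_cols <- intersect(names(optics), setdiff(names(stations), "station"))
  stations_an <- stations %>%
    select(-all_of(fitted_cols)) %>%
    left_join(optics, by = "station")

  # --- structural metrics (bundled morphometry) ---------------------------
  pdz <- pdz_metrics(pdz_table())

  # --- analysis subset ----------------------------------------------------
  keep <- if ("zone" %in% names(stations_an))
    !(stations_an$zone %in% config$exclude_zones) else rep(TRUE, nrow(stations_an))
  dat <- stations_an[keep, , drop = FALSE]
  y_raw <- dat[[config$response]]
  if (config$response_log) {
    if (any(y_raw <= 0))
      rl_abort("response must be positive for the log transform", "domain_error")
    y <- log(y_raw)
  } else y <- y_raw

  # --- AEM ----------------------------------------------------------------
  inc <- aem_incidence(graph)[dat$station, , drop = FALSE]
  basis <- aem_basis(inc)
  selection <- aem_forward_select(basis, y, alpha = config$alpha,
                                  n_permutations = config$n_permutations,
                                  seed = config$seed)
  Xs <- aem_selected_matrix(basis, selection)
  say("aem", paste(ncol(basis$vectors), "eigenfunctions,",
                   length(selection$selected), "retained"))

  # --- environmental screening + model ranking ---------------------------
  env_cols <- intersect(config$env, names(dat))
  Xe_full <- dat[, env_cols, drop = FALSE]
  screen <- vif_screen(Xe_full, threshold = config$vif_threshold)
  Xe <- screen$retained
  subsets <- best_subsets(Xe, y, max_size = min(config$max_size, ncol(Xe)))
  say("select", paste("best model:", subsets$fits$predictors[1]))

  # --- partitioning + importance ------------------------------------------
  part <- partition_variation(y, Xs, Xe, adjusted = config$adjusted)
  best_vars <- subsets$fits$vars[[1]]
  importance <- despatialized_importance(y, Xs, Xe[, best_vars, drop = FALSE])
  say("partition", paste("pure spatial =",
                         signif(part$fractions$value[1], 3)))

  # --- descriptive longitudinal smoothing ---------------------------------
  smooth <- NULL
  if ("distance_km" %in% names(dat) && nrow(dat) >= 10) {
    smooth <- smooth_longitudinal(y, dat$distance_km, span = config$loess_span)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("riverlight")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_stations = nrow(stations), n_analysed = nrow(dat)
  )
  run <- structure(
    list(stations = stations_an, graph = graph, optics = optics, pdz = pdz,
         aem = list(basis = basis, selection = selection),
         screen = screen, subsets = subsets, partition = part,
         importance = importance, smooth = smooth, provenance = provenance),
    class = "riverscape_run"
  )
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.riverscape_run <- function(x, ...) {
  cat("<riverscape_run> ", x$provenance$n_analysed, "/",
      x$provenance$n_stations, " stations analysed; ",
      length(x$aem$selection$selected), " AEM eigenfunctions retained\n",
      sep = "")
  print(x$partition)
  invisible(x)
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$stations, file.path(outdir, "stations_optics.csv"))
  readr::write_csv(run$pdz, file.path(outdir, "pdz_metrics.csv"))
  readr::write_csv(run$subsets$fits %>% select(-"vars"),
                   file.path(outdir, "best_subsets.csv"))
  readr::write_csv(run$importance$shares, file.path(outdir, "importance.csv"))
  jsonlite::write_json(
    list(fractions = run$partition$fractions, r2 = as.list(run$partition$r2),
         adjusted = run$partition$adjusted),
    file.path(outdir, "partition.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(steps = run$aem$selection$steps,
         selected = run$aem$selection$selected,
         n_eigenfunctions = ncol(run$aem$basis$vectors)),
    file.path(outdir, "aem_selection.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$provenance, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Descriptive longitudinal smoothing
#'
#' Local linear regression (loess, degree 1, tricube weights, exact direct
#' surface) of a variable against downstream distance. Descriptive only --
#' the smoothed curve never feeds inference.
#'
#' @param values Numeric vector (>= 10 points).
#' @param distance_km Downstream distance of each point.
#' @param span Smoothing span in (0, 1].
#' @return Tibble `distance_km`, `value`, `smoothed`, ordered by distance.
#' @export
smooth_longitudinal <- function(values, distance_km, span = 0.5) {
  if (length(values) < 10)
    rl_abort("longitudinal smoothing needs >= 10 points", "domain_error")
  if (span <= 0 || span > 1)
    rl_abort("span must lie in (0, 1]", "domain_error")
  ord <- order(distance_km)
  d <- data.frame(x = distance_km[ord], y = values[ord])
  fit <- loess(y ~ x, data = d, span = span, degree = 1,
               surface = "direct", family = "gaussian")
  tibble(distance_km = d$x, value = d$y, smoothed = predict(fit))
}

#' Longitudinal profile plot with loess smooth
#'
#' @param stations Station tibble with `distance_km`.
#' @param var Column to plot (string).
#' @param span Loess span.
#' @return A ggplot.
#' @export
plot_longitudinal <- function(stations, var, span = 0.5) {
  sm <- smooth_longitudinal(stations[[var]], stations$distance_km, span = span)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$distance_km)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "firebrick") +
    ggplot2::labs(x = "distance downstream (km)", y = var) +
    ggplot2::theme_minimal()
}
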