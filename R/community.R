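#' True underwater color ratios from latent band attenuation
#'
#' Color ratios are defined as ratios of attenuation reciprocals:
#' `blue_red = Kd(red)/Kd(blue)` (equivalently the ratio of 1% penetration
#' depths), so values > 1 mean blue penetrates deeper than red.
#'
#' @param kd_tab Tibble `station`, `band`, `kd` from [latent_kd()].
#' @return Tibble `station`, `blue_red`, `green_red`.
#' @export
true_color_ratios <- function(kd_tab) {
  kd_tab %>%
    tidyr::pivot_wider(names_from = "band", values_from = "kd") %>%
    mutate(blue_red = .data$red / .data$blue,
           green_red = .data$red / .data$green) %>%
    select("station", "blue_red", "green_red")
}

#' Generate the phytoplankton community response
#'
#' The cyanobacteria/eukaryote balance responds log-linearly to underwater
#' color and nutrients:
#' `ln(cyano/euk) = beta0 + beta_color * ln(blue_red) + beta_srp * ln(SRP) + eps`.
#' Residuals `eps` are white noise, or, when `config$community$rho > 0`,
#' propagated downstream along the graph as an AR(1) process
#' (`eps = rho * mean(parent eps) + sqrt(1 - rho^2) * innovation`), giving the
#' community a purely spatial variance component. Cell densities are
#' back-transformed to positive counts and split into pico/nano size classes.
#'
#' @param concentrations Tibble from [mix_downstream()] (supplies SRP).
#' @param color_ratios Tibble from [true_color_ratios()] (or measured ratios).
#' @param config A [river_config()].
#' @param graph The [river_graph()]; required when `rho != 0`.
#' @return Tibble per station: `cyano_euk`, `picocyano`, `nanocyano`,
#'   `picoeuk`, `nanoeuk` (cells mL^-1), `chla` (ug L^-1).
#' @export
generate_community <- function(concentrations, color_ratios, config,
                               graph = NULL) {
  cm <- config$community
  dat <- concentrations %>% left_join(color_ratios, by = "station")
  if (any(dat$srp <= 0))
    rl_abort("SRP must be positive before log transform", "domain_error")
  if (any(dat$blue_red <= 0))
    rl_abort("color ratio must be positive before log transform", "domain_error")
  rho <- cm$rho %||% 0
  n <- nrow(dat)
  if (rho != 0) {
    if (is.null(graph))
      rl_abort("graph required to propagate autocorrelated residuals",
               "config_error")
    eps <- graph_ar1(graph, rho, cm$noise_sd)[dat$station]
  } else {
    eps <- rnorm(n, sd = cm$noise_sd)
  }
  ln_ratio <- unname(cm$beta0 + cm$beta_color * log(dat$blue_red) +
                       cm$beta_srp * log(dat$srp) + eps)
  euk_total <- exp(rnorm(n, mean = log(4000), sd = 0.4))
  cyano_total <- euk_total * exp(ln_ratio)
  pc_frac <- stats::plogis(stats::qlogis(0.85) + rnorm(n, sd = 0.3))
  pe_frac <- stats::plogis(stats::qlogis(0.35) + rnorm(n, sd = 0.3))
  total <- euk_total + cyano_total
  tibble(
    station = dat$station,
    cyano_euk = exp(ln_ratio),
    picocyano = cyano_total * pc_frac,
    nanocyano = cyano_total * (1 - pc_frac),
    picoeuk = euk_total * pe_frac,
    nanoeuk = euk_total * (1 - pe_frac),
    chla = 1e-3 * total * exp(rnorm(n, sd = 0.2))
  )
}

# AR(1) residuals propagated downstream: each station inherits rho times the
# mean residual of its station parents plus a fresh innovation
graph_ar1 <- function(graph, rho, sd) {
  ig <- as_igraph(graph)
  ord <- names(igraph::topo_sort(ig, mode = "out"))
  origins <- origin_ids(graph)
  eps <- setNames(numeric(length(ord)), ord)
  for (node in ord) {
    if (node %in% origins) next
    parents <- setdiff(graph$edges$parent[graph$edges$child == node], origins)
    innov <- rnorm(1, sd = sd)
    if (length(parents) == 0) {
      eps[node] <- innov
    } else {
      eps[node] <- rho * mean(eps[parents]) + sqrt(1 - rho^2) * innov
    }
  }
  eps[station_ids(graph)]
}

#' Simulate a complete synthetic river
#'
#' Runs the whole generator in a documented order under a single seed:
#' network, downstream mixing, station water depths, physical covariates,
#' light profiles, then the community response. Regenerating with the same
#' config reproduces every field bit-identically.
#'
#' @param config A [river_config()].
#' @param profiles Generate spectral depth profiles? (They dominate run time
#'   and memory; stages that only need latent truth can skip them.)
#' @return A list of class `river_simulation`: `config`, `graph`,
#'   `stations` (one row per station: position, chemistry, true Kd per band,
#'   true color ratios, covariates, community), `profiles` (long tibble or
#'   `NULL`), `truth` (latent concentrations, Kd, betas, seed).
#' @export
#' @examples
#' sim <- simulate_river(river_config(n_transects = 4, seed = 7),
#'                       profiles = FALSE)
#' head(sim$stations)
simulate_river <- function(config, profiles = TRUE) {
  config <- validate_river_config(config)
  set.seed(config$seed)
  graph <- generate_network(config)
  conc <- mix_downstream(graph, config)
  kd_tab <- latent_kd(conc, config)
  ratios <- true_color_ratios(kd_tab)
  n <- nrow(conc)

  # draw order under the single seed: (1) local SRP variability, (2) station
  # depths, (3) covariates, (4) profile noise, (5) community noise
  srp_sd <- config$srp_local_sd %||% 0
  if (srp_sd > 0) conc$srp <- conc$srp * exp(rnorm(n, sd = srp_sd))
  water_depth <- runif(n, config$depth_range[1], config$depth_range[2])
  st_meta <- graph$nodes %>% filter(.data$type == "station") %>%
    select(station = "node", "transect", "lane", "distance_km")
  covars <- tibble(
    station = conc$station,
    water_depth_m = water_depth,
    turbidity = 0.8 * conc$tripton * exp(rnorm(n, sd = 0.1)),
    transmittance = 100 * exp(-0.12 * conc$tripton) * exp(rnorm(n, sd = 0.05)),
    temperature = 22 - 0.004 * st_meta$distance_km + rnorm(n, sd = 0.3),
    conductivity = 300 - 6 * conc$acdom + rnorm(n, sd = 5)
  )
  prof <- if (profiles) generate_profiles(conc, config) else NULL
  comm <- generate_community(conc, ratios, config, graph = graph)

  stations <- st_meta %>%
    left_join(conc, by = "station") %>%
    left_join(ratios, by = "station") %>%
    left_join(kd_tab %>%
                tidyr::pivot_wider(names_from = "band", values_from = "kd",
                                   names_prefix = "kd_"),
              by = "station") %>%
    left_join(covars, by = "station") %>%
    left_join(comm, by = "station") %>%
    mutate(zone = "main")

  structure(
    list(config = config, graph = graph, stations = stations,
         profiles = prof,
         truth = list(concentrations = conc, kd = kd_tab, ratios = ratios,
                      community = config$community, seed = config$seed)),
    class = "river_simulation"
  )
}

#' @export
print.river_simulation <- function(x, ...) {
  cat("<river_simulation> seed ", x$config$seed, ": ",
      nrow(x$stations), " stations",
      if (!is.null(x$profiles)) paste0(", ", nrow(x$profiles), " profile rows"),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated river to disk
#'
#' Emits the station table CSV, the long-format profile CSV (if generated),
#' the graph as edge-list TSV and GraphML, and the latent truth as JSON.
#'
#' @param sim A `river_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$stations, file.path(dir, "stations.csv"))
  if (!is.null(sim$profiles))
    readr::write_csv(sim$profiles, file.path(dir, "profiles.csv"))
  write_edge_list(sim$graph, file.path(dir, "graph_edges.tsv"))
  write_graphml(sim$graph, file.path(dir, "graph.graphml"))
  jsonlite::write_json(
    list(concentrations = sim$truth$concentrations,
         kd = sim$truth$kd, ratios = sim$truth$ratios,
         community = sim$truth$community, seed = sim$truth$seed),
    file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
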