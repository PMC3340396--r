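# small configurations and profiles used across test files

tiny_config <- function(seed = 1L, depth_step = 0.1, profile_max_depth = 2,
                        ...) {
  river_config(
    n_transects = 4, stations_per_transect = 2,
    tributaries = tibble::tibble(
      name = "trib_a", transect = 2L, lane = 1L,
      discharge = 500, acdom = 20, tripton = 6, srp = 30),
    transect_spacing_km = 20,
    depth_step = depth_step, profile_max_depth = profile_max_depth,
    seed = seed, ...
  )
}

# noiseless single-station profile with known per-band attenuation
exp_profile <- function(kd, depths = seq(0, 2, by = 0.1), ed0 = 100,
                        wavelengths = seq(351, 750, 3), station = "S1") {
  kd_wl <- if (length(kd) == 1) rep(kd, length(wavelengths)) else kd
  tidyr::expand_grid(station = station, depth_m = depths,
                     wavelength_nm = wavelengths) |>
    dplyr::mutate(ed = ed0 * exp(-kd_wl[match(wavelength_nm, wavelengths)] * depth_m))
}

# hand-built 6-station, 2-tributary tree used by the AEM oracle tests:
# o -> s1 -> s2 -> s3 -> s4, t1 -> s2, t2 -> s4, s2 -> s5, s5 -> s6
six_station_graph <- function() {
  river_graph(data.frame(
    parent = c("o", "s1", "s2", "s3", "t1", "t2", "s2", "s5"),
    child  = c("s1", "s2", "s3", "s4", "s2", "s4", "s5", "s6")
  ))
}

# trapezoid rule on an arbitrary grid (fine-grid quadrature oracle)
pracma_trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# orthonormal columns that are also centered (orthogonal to the intercept)
centered_orthogonal <- function(n, p) {
  qr.Q(qr(cbind(1, matrix(rnorm(n * p), n))))[, -1, drop = FALSE]
}

# all permutations of 1..n (recursive, for brute-force lmg oracles)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (s in sub) for (pos in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(s, n, after = pos)
  }
  out
}

# random rooted tree on n stations plus an origin, seeded
random_tree_graph <- function(n, seed) {
  set.seed(seed)
  parents <- c("o", vapply(2:n, function(i)
    paste0("s", sample.int(i - 1, 1)), character(1)))
  river_graph(data.frame(parent = parents, child = paste0("s", 1:n)))
}
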