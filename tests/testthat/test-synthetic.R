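# synthetic river generator: network construction, conservative mixing,
# light-profile inversion, and the community response

test_that("smallest network is one origin, one station, one edge", {
  cfg <- river_config(n_transects = 1, stations_per_transect = 1,
                      tributaries = NULL, seed = 1)
  g <- generate_network(cfg)
  expect_length(origin_ids(g), 1)
  expect_length(station_ids(g), 1)
  expect_equal(nrow(g$edges), 1)
})

test_that("network construction is deterministic and matches the hand count", {
  cfg <- river_config(n_transects = 16, stations_per_transect = 3, seed = 9)
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  expect_identical(g1$edges, g2$edges)
  expect_length(station_ids(g1), 48)
  # by construction: 3 head edges + 3 lanes x 15 chain edges + 5 tributary edges
  expect_equal(nrow(g1$edges), 3 + 3 * 15 + 5)
  # DAG with every station reachable holds by river_graph validation
  expect_s3_class(g1, "river_graph")
})

test_that("invalid graphs are rejected", {
  expect_error(
    river_graph(data.frame(parent = c("a", "b"), child = c("b", "a"))),
    class = "structural_error")
  bad_trib <- tibble::tibble(name = "x", transect = 99L, lane = 1L,
                             discharge = 1, acdom = 1, tripton = 1, srp = 1)
  expect_error(river_config(n_transects = 2, tributaries = bad_trib),
               class = "config_error")
})

test_that("confluence mixing is discharge-weighted and conservative", {
  # two equal inflows with concentrations 10 and 20 mix to 15
  g <- river_graph(data.frame(parent = c("O_main", "O_t"), child = c("S001", "S001")))
  cfg <- river_config(
    n_transects = 1, stations_per_transect = 1,
    tributaries = tibble::tibble(name = "t", transect = 1L, lane = 1L,
                                 discharge = 100, acdom = 20, tripton = 20,
                                 srp = 20),
    main_discharge = 100,
    main_endmember = list(acdom = 10, tripton = 10, srp = 10), seed = 1)
  conc <- mix_downstream(g, cfg)
  expect_equal(conc$acdom, 15)
  expect_equal(conc$discharge, 200)

  # single-source river: every station equals the source endmember
  cfg1 <- river_config(n_transects = 5, stations_per_transect = 2,
                       tributaries = NULL, seed = 1)
  conc1 <- mix_downstream(generate_network(cfg1), cfg1)
  expect_true(all(conc1$acdom == cfg1$main_endmember$acdom))
  expect_true(all(conc1$srp == cfg1$main_endmember$srp))
})

test_that("three-tributary chain matches a hand-propagated mass balance", {
  tribs <- tibble::tibble(
    name = c("t1", "t2", "t3"), transect = c(2L, 3L, 4L), lane = 1L,
    discharge = c(100, 200, 50),
    acdom = c(20, 5, 40), tripton = c(4, 1, 8), srp = c(30, 10, 60))
  cfg <- river_config(n_transects = 4, stations_per_transect = 1,
                      tributaries = tribs, main_discharge = 1000,
                      main_endmember = list(acdom = 2, tripton = 1, srp = 5),
                      seed = 1)
  conc <- mix_downstream(generate_network(cfg), cfg)
  # spreadsheet-style propagation, independent arithmetic
  q1 <- 1000; a1 <- 2
  q2 <- q1 + 100; a2 <- (q1 * a1 + 100 * 20) / q2
  q3 <- q2 + 200; a3 <- (q2 * a2 + 200 * 5) / q3
  q4 <- q3 + 50;  a4 <- (q3 * a3 + 50 * 40) / q4
  expect_equal(conc$discharge, c(q1, q2, q3, q4))
  expect_equal(conc$acdom, c(a1, a2, a3, a4))
  # mass-flux conservation at every confluence, all constituents
  for (v in c("acdom", "tripton", "srp")) {
    flux_in <- 1000 * cfg$main_endmember[[v]] + sum(tribs$discharge * tribs[[v]])
    flux_out <- conc$discharge[4] * conc[[v]][4]
    expect_equal(flux_out, flux_in, tolerance = 1e-10)
  }
})

test_that("zero total discharge raises an arithmetic error", {
  g <- river_graph(data.frame(parent = "O_main", child = "S001"))
  cfg <- river_config(n_transects = 1, stations_per_transect = 1,
                      tributaries = NULL, seed = 1)
  cfg$main_discharge <- 0 # bypass constructor validation on purpose
  expect_error(mix_downstream(g, cfg), class = "config_error")
})

test_that("noiseless profiles invert exactly and are anchored at the surface", {
  cfg <- tiny_config(profile_noise_sd = 0)
  conc <- tibble::tibble(station = "S001", discharge = 1,
                         acdom = 3, tripton = 2, srp = 10)
  prof <- generate_profiles(conc, cfg)
  kd_truth <- latent_kd(conc, cfg)
  # ln Ed vs depth slope equals -Kd at every wavelength inside a band
  blue <- prof[prof$wavelength_nm == 450, ]
  slope <- coef(lm(log(ed) ~ depth_m, blue))[2]
  expect_equal(unname(slope), -kd_truth$kd[kd_truth$band == "blue"],
               tolerance = 1e-12)
  # z = 0 returns the surface spectrum
  expect_equal(prof$ed[prof$depth_m == 0],
               rep(100, sum(prof$depth_m == 0)), tolerance = 1e-12)
})

test_that("noisy profiles recover Kd within Monte-Carlo error", {
  cfg <- tiny_config(profile_noise_sd = 0.05, depth_step = 0.02,
                     profile_max_depth = 2)
  conc <- tibble::tibble(station = "S001", discharge = 1,
                         acdom = 3, tripton = 2, srp = 10)
  truth <- latent_kd(conc, cfg)
  kd_true <- truth$kd[truth$band == "green"]
  set.seed(42)
  reps <- 50
  est <- replicate(reps, {
    prof <- generate_profiles(conc, cfg)
    fit_kd(prof, "green")$kd
  })
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - kd_true), 3 * se + 1e-6)
})

test_that("community response honours the null model and recovers beta", {
  cfg <- tiny_config()
  cfg$community <- list(beta0 = 0.7, beta_color = 0, beta_srp = 0,
                        noise_sd = 0, rho = 0)
  conc <- mix_downstream(generate_network(cfg), cfg)
  ratios <- true_color_ratios(latent_kd(conc, cfg))
  comm <- generate_community(conc, ratios, cfg)
  expect_equal(comm$cyano_euk, rep(exp(0.7), nrow(comm)), tolerance = 1e-12)
  expect_true(all(comm$picocyano > 0 & comm$nanoeuk > 0))

  # estimation consistency at n = 200: OLS on the true predictors
  cfg2 <- river_config(n_transects = 50, stations_per_transect = 4,
                       seed = 11)
  sim <- simulate_river(cfg2, profiles = FALSE)
  fit <- lm(log(cyano_euk) ~ log(blue_red) + log(srp), sim$stations)
  expect_lt(abs(coef(fit)[2] - cfg2$community$beta_color),
            0.1 * cfg2$community$beta_color)
})

test_that("nonpositive SRP or ratio errors before the log", {
  cfg <- tiny_config()
  conc <- tibble::tibble(station = "S001", discharge = 1, acdom = 1,
                         tripton = 1, srp = 0)
  ratios <- tibble::tibble(station = "S001", blue_red = 1, green_red = 1)
  expect_error(generate_community(conc, ratios, cfg), class = "domain_error")
})

test_that("autocorrelated residuals show up along the graph", {
  cfg <- river_config(n_transects = 40, stations_per_transect = 3,
                      seed = 5)
  cfg$community$rho <- 0.8
  sim <- simulate_river(cfg, profiles = FALSE)
  st <- sim$stations
  res <- resid(lm(log(cyano_euk) ~ log(blue_red) + log(srp), st))
  # lag-1 correlation along each lane chain, permutation test
  by_lane <- split(seq_len(nrow(st))[order(st$lane, st$transect)],
                   st$lane[order(st$lane, st$transect)])
  lag_cor <- function(r) {
    pairs <- do.call(rbind, lapply(by_lane, function(ix)
      cbind(r[ix][-length(ix)], r[ix][-1])))
    cor(pairs[, 1], pairs[, 2])
  }
  obs <- lag_cor(res)
  set.seed(99)
  null <- replicate(499, lag_cor(sample(res)))
  p <- (sum(null >= obs) + 1) / 500
  expect_lt(p, 0.05)
})

test_that("regenerating with the same seed is bit-identical, different seed differs", {
  cfg <- tiny_config(seed = 21)
  s1 <- simulate_river(cfg, profiles = TRUE)
  s2 <- simulate_river(cfg, profiles = TRUE)
  expect_identical(s1$stations, s2$stations)
  expect_identical(s1$profiles, s2$profiles)
  s3 <- simulate_river(tiny_config(seed = 22), profiles = FALSE)
  expect_false(identical(s1$stations$cyano_euk, s3$stations$cyano_euk))
})

test_that("optical monotonicity: blue/red strictly decreases with aCDOM", {
  cfg <- tiny_config()
  conc <- tibble::tibble(station = paste0("S", 1:6), discharge = 1,
                         acdom = seq(1, 26, by = 5), tripton = 2, srp = 10)
  ratios <- true_color_ratios(latent_kd(conc, cfg))
  expect_true(all(diff(ratios$blue_red) < 0))
})

test_that("simulation round-trips through its file formats", {
  dir <- withr::local_tempdir()
  sim <- simulate_river(tiny_config(seed = 4), profiles = FALSE)
  write_simulation(sim, dir)
  g <- read_edge_list(file.path(dir, "graph_edges.tsv"))
  expect_equal(nrow(g$edges), nrow(sim$graph$edges))
  g2 <- read_graphml(file.path(dir, "graph.graphml"))
  expect_setequal(station_ids(g2), station_ids(sim$graph))
  st <- readr::read_csv(file.path(dir, "stations.csv"), show_col_types = FALSE)
  expect_equal(st$cyano_euk, sim$stations$cyano_euk, tolerance = 1e-12)
})
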