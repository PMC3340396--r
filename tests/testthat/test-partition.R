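# two-table variation partitioning and lmg hierarchical importance

test_that("partition fractions satisfy the Venn identities", {
  set.seed(1)
  n <- 80
  Xs <- matrix(rnorm(n * 3), n)
  Xe <- matrix(rnorm(n * 4), n)
  y <- Xs[, 1] + Xe[, 1] - 0.5 * Xe[, 2] + rnorm(n)
  for (adj in c(TRUE, FALSE)) {
    p <- partition_variation(y, Xs, Xe, adjusted = adj)
    f <- setNames(p$fractions$value, p$fractions$fraction)
    expect_equal(unname(f["pure_spatial"] + f["shared"]), p$r2[["spatial"]],
                 tolerance = 1e-10)
    expect_equal(unname(f["pure_environmental"] + f["shared"]), p$r2[["env"]],
                 tolerance = 1e-10)
    expect_equal(unname(f["pure_spatial"] + f["pure_environmental"] +
                          f["shared"]), p$r2[["both"]], tolerance = 1e-10)
    expect_equal(unname(f["residual"]), 1 - p$r2[["both"]], tolerance = 1e-10)
  }
})

test_that("total confounding puts everything in the shared fraction", {
  set.seed(2)
  X <- matrix(rnorm(60 * 2), 60)
  y <- X[, 1] + rnorm(60, sd = 0.3)
  p <- partition_variation(y, X, X, adjusted = FALSE)
  f <- setNames(p$fractions$value, p$fractions$fraction)
  expect_equal(unname(f["pure_spatial"]), 0, tolerance = 1e-10)
  expect_equal(unname(f["pure_environmental"]), 0, tolerance = 1e-10)
  expect_gt(unname(f["shared"]), 0.5)
})

test_that("orthogonal design yields near-zero shared fraction", {
  set.seed(3)
  n <- 200
  Q <- centered_orthogonal(n, 5)
  Xs <- Q[, 1:2]
  Xe <- Q[, 3:5]
  y <- 2 * Xe[, 1] + Xe[, 2] + 0.5 * Xs[, 1] + rnorm(n, sd = 0.2)
  p <- partition_variation(y, Xs, Xe, adjusted = FALSE)
  f <- setNames(p$fractions$value, p$fractions$fraction)
  expect_lt(abs(f[["shared"]]), 0.02)
  expect_equal(f[["pure_environmental"]], p$r2[["env"]], tolerance = 0.02)
})

test_that("adjusted fractions agree with an independent partitioning oracle", {
  set.seed(21)
  n <- 100
  Xs <- matrix(rnorm(n * 3), n)
  Xe <- matrix(rnorm(n * 4), n)
  y <- Xs[, 1] - Xs[, 2] + 2 * Xe[, 1] + rnorm(n)
  p <- partition_variation(y, Xs, Xe, adjusted = TRUE)
  f <- setNames(p$fractions$value, p$fractions$fraction)
  # vegan's indfract rows are [a] pure X1, [b] pure X2, [c] shared, [d] resid
  vp <- vegan::varpart(y, Xs, Xe)$part$indfract$Adj.R.square
  expect_equal(unname(f[c("pure_spatial", "pure_environmental", "shared",
                          "residual")]),
               vp, tolerance = 1e-10)
})

test_that("a pure-noise response explains nothing beyond sampling error", {
  set.seed(4)
  n <- 150
  p <- partition_variation(rnorm(n), matrix(rnorm(n * 3), n),
                           matrix(rnorm(n * 3), n), adjusted = TRUE)
  expect_true(all(abs(p$fractions$value[1:3]) < 0.08))
})

test_that("dimension mismatches and saturated designs error", {
  expect_error(partition_variation(rnorm(10), matrix(rnorm(20), 10),
                                   matrix(rnorm(8), 4)),
               class = "contract_violation")
  expect_error(partition_variation(rnorm(6), matrix(rnorm(18), 6),
                                   matrix(rnorm(18), 6)),
               class = "contract_violation")
})

test_that("lmg equals squared marginal correlations for orthogonal predictors", {
  set.seed(5)
  n <- 120
  X <- as.data.frame(centered_orthogonal(n, 3))
  names(X) <- c("a", "b", "c")
  y <- 1.5 * X$a - 0.8 * X$b + rnorm(n, sd = 0.5)
  res <- lmg_importance(y, X)
  marginal <- vapply(X, function(x) cor(y, x)^2, numeric(1))
  expect_equal(res$shares$share, unname(marginal), tolerance = 1e-10)
  expect_equal(sum(res$shares$share), res$r2, tolerance = 1e-10)
})

test_that("lmg p = 2 closed form holds", {
  set.seed(6)
  n <- 90
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  X$b <- X$b + 0.6 * X$a
  y <- X$a + 0.5 * X$b + rnorm(n)
  res <- lmg_importance(y, X)
  r2a <- cor(y, X$a)^2
  r2b <- cor(y, X$b)^2
  r2full <- summary(lm(y ~ a + b, X))$r.squared
  expect_equal(res$shares$share[1], (r2a + (r2full - r2b)) / 2, tolerance = 1e-12)
  expect_equal(res$shares$share[2], (r2b + (r2full - r2a)) / 2, tolerance = 1e-12)
})

test_that("lmg equals the brute-force average over all orderings at p = 4", {
  set.seed(7)
  n <- 70
  Z <- matrix(rnorm(n * 4), n) %*% chol(0.5 * diag(4) + 0.5)
  X <- as.data.frame(Z)
  names(X) <- paste0("v", 1:4)
  y <- Z %*% c(1, -0.5, 0.25, 0) + rnorm(n)
  res <- lmg_importance(y, X)
  r2_of_vars <- function(vars) {
    if (length(vars) == 0) return(0)
    summary(lm(y ~ ., data = X[vars]))$r.squared
  }
  perms <- combinat_perms(4)
  shares <- numeric(4)
  for (ord in perms) {
    prev <- 0
    for (k in seq_along(ord)) {
      r2k <- r2_of_vars(names(X)[ord[seq_len(k)]])
      shares[ord[k]] <- shares[ord[k]] + (r2k - prev)
      prev <- r2k
    }
  }
  shares <- shares / length(perms)
  expect_equal(res$shares$share, shares, tolerance = 1e-12)
})

test_that("lmg is symmetric under predictor relabeling", {
  set.seed(8)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 3), n))
  names(X) <- c("a", "b", "c")
  y <- X$a + 2 * X$c + rnorm(n)
  r1 <- lmg_importance(y, X)
  r2 <- lmg_importance(y, X[, c("c", "a", "b")])
  expect_equal(setNames(r1$shares$share, r1$shares$predictor)[c("c", "a", "b")],
               setNames(r2$shares$share, r2$shares$predictor),
               tolerance = 1e-12)
})

test_that("adding a pure-noise predictor barely moves existing shares", {
  set.seed(9)
  n <- 1000
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- X$a + 0.5 * X$b + rnorm(n)
  base <- lmg_importance(y, X)
  X$junk <- rnorm(n)
  with_noise <- lmg_importance(y, X)
  expect_lt(max(abs(with_noise$shares$share[1:2] - base$shares$share)), 0.02)
})

test_that("lmg guards its enumeration limit but offers sampling", {
  X <- as.data.frame(matrix(rnorm(50 * 11), 50))
  y <- rnorm(50)
  expect_error(lmg_importance(y, X), class = "contract_violation")
  res <- lmg_importance(y, X, sample_orderings = 20, seed = 1)
  expect_equal(sum(res$shares$share), summary(lm(y ~ ., X))$r.squared,
               tolerance = 1e-8)
})

test_that("despatialized importance reduces and saturates correctly", {
  set.seed(10)
  n <- 100
  Xe <- as.data.frame(matrix(rnorm(n * 3), n))
  names(Xe) <- c("e1", "e2", "e3")
  y <- Xe$e1 + rnorm(n)
  # empty spatial basis: identical to plain lmg
  empty <- matrix(numeric(0), nrow = n, ncol = 0)
  d0 <- despatialized_importance(y, empty, Xe)
  l0 <- lmg_importance(y, Xe)
  expect_equal(d0$shares$share_partial, l0$shares$share, tolerance = 1e-12)

  # response fully spanned by the spatial basis: degenerate, reported
  Xs <- cbind(y, rnorm(n))
  expect_error(despatialized_importance(y, Xs, Xe), class = "degenerate_error")

  # response driven only by space: environmental shares collapse
  Xs2 <- matrix(rnorm(n * 2), n)
  y2 <- Xs2[, 1] + 0.01 * rnorm(n)
  d2 <- despatialized_importance(y2, Xs2, Xe)
  expect_lt(sum(d2$shares$share_total), 0.05)
})

test_that("despatialized lmg shares sum to the pure environmental fraction", {
  set.seed(11)
  n <- 120
  Xs <- matrix(rnorm(n * 3), n)
  Xe <- as.data.frame(matrix(rnorm(n * 3), n))
  names(Xe) <- paste0("e", 1:3)
  y <- Xs[, 1] + Xe$e1 - Xe$e2 + rnorm(n)
  d <- despatialized_importance(y, Xs, Xe)
  p <- partition_variation(y, Xs, Xe, adjusted = FALSE)
  pure_env <- p$fractions$value[p$fractions$fraction == "pure_environmental"]
  expect_equal(sum(d$shares$share_total), pure_env, tolerance = 1e-10)
})

test_that("pure spatial fraction grows with residual autocorrelation", {
  mean_pure_spatial <- function(rho, seeds) {
    vals <- vapply(seeds, function(s) {
      cfg <- river_config(n_transects = 25, stations_per_transect = 3,
                          seed = s)
      cfg$community$rho <- rho
      sim <- simulate_river(cfg, profiles = FALSE)
      st <- sim$stations
      y <- log(st$cyano_euk)
      basis <- aem_basis(aem_incidence(sim$graph)[st$station, ])
      sel <- aem_forward_select(basis, y, n_permutations = 99, seed = s)
      Xs <- aem_selected_matrix(basis, sel)
      if (ncol(Xs) == 0) Xs <- basis$vectors[, 1, drop = FALSE]
      Xe <- data.frame(br = log(st$blue_red), srp = log(st$srp))
      p <- partition_variation(y, Xs, Xe, adjusted = TRUE)
      p$fractions$value[p$fractions$fraction == "pure_spatial"]
    }, numeric(1))
    mean(vals)
  }
  seeds <- 301:306
  low <- mean_pure_spatial(0, seeds)
  high <- mean_pure_spatial(0.9, seeds)
  expect_gt(high, low)
})

test_that("tidiers expose fractions and shares as tibbles", {
  set.seed(12)
  n <- 50
  Xs <- matrix(rnorm(n * 2), n)
  Xe <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- Xe$a + rnorm(n)
  p <- partition_variation(y, Xs, Xe)
  expect_s3_class(tidy(p), "tbl_df")
  expect_equal(nrow(glance(p)), 1)
  l <- lmg_importance(y, Xe)
  expect_s3_class(tidy(l), "tbl_df")
  expect_s3_class(autoplot(l), "ggplot")
  expect_s3_class(autoplot(p), "ggplot")
})
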