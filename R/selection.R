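#' Box-Cox normalizing transformation
#'
#' Chooses lambda by profile maximum likelihood on a fixed grid
#' (default -3 to 3 in steps of 0.01) and applies the power transform
#' `(x^lambda - 1) / lambda`, or `ln x` at lambda = 0.
#'
#' @param x Positive numeric vector.
#' @param lambda Optional fixed lambda (skips the search).
#' @param grid Candidate lambdas for the likelihood search.
#' @return List of class `box_cox`: `values` (transformed vector), `lambda`,
#'   and `profile` (tibble of `lambda`, `loglik`; `NULL` when lambda fixed).
#' @export
#' @examples
#' bc <- box_cox(rlnorm(50))
#' bc$lambda
box_cox <- function(x, lambda = NULL, grid = seq(-3, 3, by = 0.01)) {
  bad <- which(x <= 0 | !is.finite(x))
  if (length(bad))
    rl_abort(paste("box_cox requires positive values; offending rows:",
                   paste(head(bad, 10), collapse = ", ")), "domain_error")
  transform <- function(l) if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
  profile <- NULL
  if (is.null(lambda)) {
    n <- length(x)
    slx <- sum(log(x))
    ll <- vapply(grid, function(l) {
      y <- transform(l)
      -n / 2 * log(sum((y - mean(y))^2) / n) + (l - 1) * slx
    }, numeric(1))
    lambda <- grid[which.max(ll)]
    profile <- tibble(lambda = grid, loglik = ll)
  }
  structure(list(values = transform(lambda), lambda = lambda,
                 profile = profile),
            class = "box_cox")
}

#' @export
print.box_cox <- function(x, ...) {
  cat("<box_cox> lambda =", x$lambda, "\n")
  invisible(x)
}

#' Variance inflation factor screening
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j on
#' all others (with intercept). Predictors are dropped one at a time --
#' always the largest VIF -- until every VIF is at or below the threshold.
#' Perfect collinearity (infinite VIF) is dropped immediately.
#'
#' @param X Data frame / tibble of numeric predictors (>= 2 columns, n > p).
#' @param threshold Maximum tolerated VIF (default 5).
#' @return List of class `vif_screen`: `retained` (tibble of kept
#'   predictors), `kept` (names), `dropped` (names, drop order), and
#'   `report` (tibble of `round`, `predictor`, `vif`, `dropped`).
#' @export
vif_screen <- function(X, threshold = 5) {
  X <- as_tibble(X)
  if (ncol(X) < 2) rl_abort("vif_screen needs >= 2 predictors", "domain_error")
  if (nrow(X) <= ncol(X))
    rl_abort("vif_screen needs n > p", "contract_violation")
  vif_of <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      fit <- lm.fit(cbind(1, as.matrix(M[, -j, drop = FALSE])),
                    M[[j]])
      ssr <- sum(fit$residuals^2)
      sst <- sum((M[[j]] - mean(M[[j]]))^2)
      r2 <- 1 - ssr / sst
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- X
  dropped <- character(0)
  report <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    v <- vif_of(keep)
    worst <- which.max(v)
    drop_now <- v[worst] > threshold && ncol(keep) > 1
    report[[round_i]] <- tibble(round = round_i, predictor = names(keep),
                                vif = v,
                                dropped = drop_now &
                                  seq_along(v) == worst)
    if (!drop_now) break
    dropped <- c(dropped, names(keep)[worst])
    keep <- keep[, -worst, drop = FALSE]
    if (ncol(keep) < 2) break
  }
  structure(list(retained = keep, kept = names(keep), dropped = dropped,
                 report = bind_rows(report)),
            class = "vif_screen")
}

#' @export
print.vif_screen <- function(x, ...) {
  cat("<vif_screen> kept", length(x$kept), "of",
      length(x$kept) + length(x$dropped), "predictors")
  if (length(x$dropped)) cat(" (dropped:", paste(x$dropped, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Exhaustive best-subsets regression
#'
#' For every subset size k up to `max_size`, finds the predictor subset
#' minimizing the residual sum of squares over all C(p, k) subsets (full
#' enumeration). Ties are broken lexicographically by predictor name. Sizes
#' with too few observations are skipped with a warning.
#'
#' @param X Data frame / tibble of numeric predictors (p <= 15).
#' @param y Numeric response.
#' @param max_size Largest subset size considered (default p).
#' @return Object of class `best_subsets`: tibble `fits` with one row per
#'   size: `size`, `predictors` (comma string), `vars` (list), `rss`, `r2`,
#'   `n`, `p` (coefficients incl. intercept), `aic`, `delta_aic`.
#' @export
#' @examples
#' X <- data.frame(a = rnorm(30), b = rnorm(30))
#' best_subsets(X, X$a + rnorm(30, sd = 0.1))
best_subsets <- function(X, y, max_size = ncol(X)) {
  X <- as_tibble(X)
  p <- ncol(X)
  if (p > 15)
    rl_abort("exhaustive enumeration limited to p <= 15 predictors",
             "contract_violation")
  n <- length(y)
  Xm <- as.matrix(X)
  nm <- colnames(Xm)
  ss_tot <- sum((y - mean(y))^2)
  rows <- list()
  for (k in seq_len(min(max_size, p))) {
    if (n <= k + 1) {
      warn(sprintf("size %d skipped: n <= p", k))
      next
    }
    combos <- combn(p, k)
    # lexicographic-by-name candidate order so that the first minimum wins ties
    ord <- order(apply(combos, 2, function(ix) paste(sort(nm[ix]), collapse = ",")))
    combos <- combos[, ord, drop = FALSE]
    best_rss <- Inf
    best_ix <- NULL
    for (ci in seq_len(ncol(combos))) {
      ix <- combos[, ci]
      fit <- lm.fit(cbind(1, Xm[, ix, drop = FALSE]), y)
      rss <- sum(fit$residuals^2)
      if (rss < best_rss - 1e-12) {
        best_rss <- rss
        best_ix <- ix
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      size = k,
      predictors = paste(sort(nm[best_ix]), collapse = " + "),
      vars = list(nm[best_ix]),
      rss = best_rss,
      r2 = 1 - best_rss / ss_tot,
      n = n,
      p = k + 1L
    )
  }
  fits <- aic_rank(bind_rows(rows))
  structure(list(fits = fits), class = "best_subsets")
}

#' @export
print.best_subsets <- function(x, ...) {
  print(x$fits %>% select("size", "predictors", "r2", "aic", "delta_aic"))
  invisible(x)
}

#' @export
tidy.best_subsets <- function(x, ...) x$fits

#' Rank model fits by AIC
#'
#' Uses the Gaussian profile form `AIC = n ln(RSS/n) + 2 (p + 1)` (p =
#' coefficients including the intercept; + 1 for the error variance) when RSS
#' is available, or accepts precomputed `aic` values directly. Returns models
#' ascending in AIC with `delta_aic = AIC_i - min AIC` (0 for the best model,
#' ties allowed).
#'
#' @param models Tibble with either column `aic`, or columns `rss`, `n`, `p`.
#' @return The tibble with `aic` and `delta_aic`, sorted ascending by AIC.
#' @export
#' @examples
#' aic_rank(data.frame(aic = c(-39.93, 8.14, -10.78)))$delta_aic
aic_rank <- function(models) {
  models <- as_tibble(models)
  if (!"aic" %in% names(models)) {
    if (!all(c("rss", "n", "p") %in% names(models)))
      rl_abort("models need either aic, or rss + n + p", "contract_violation")
    if (length(unique(models$n)) > 1)
      rl_abort("AIC comparison requires a common n across models",
               "contract_violation")
    models$aic <- models$n * log(models$rss / models$n) + 2 * (models$p + 1)
  }
  models %>%
    mutate(delta_aic = .data$aic - min(.data$aic)) %>%
    arrange(.data$aic)
}
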