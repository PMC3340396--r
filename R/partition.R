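r2_of <- function(y, X, adjusted = FALSE) {
  X <- as.matrix(X)
  n <- length(y)
  if (ncol(X) == 0) return(0)
  fit <- lm.fit(cbind(1, X), y)
  rank_x <- fit$rank - 1L
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  if (adjusted) r2 <- 1 - (1 - r2) * (n - 1) / (n - 1 - rank_x)
  r2
}

#' Two-table variation partitioning (spatial vs environmental)
#'
#' Fits the three regressions of the response on the spatial predictors, the
#' environmental predictors, and their union, and decomposes explained
#' variance into the classic Venn fractions: pure spatial
#' (`R2(both) - R2(env)`), pure environmental (`R2(both) - R2(spatial)`),
#' shared (`R2(spatial) + R2(env) - R2(both)`), and residual
#' (`1 - R2(both)`). Adjusted R-squared is the default, as usual for
#' two-table ecological partitioning; small negative adjusted fractions are
#' reported as-is, never clipped.
#'
#' @param y Numeric response.
#' @param X_spatial Matrix/data frame of spatial predictors (e.g. selected
#'   AEM eigenfunctions).
#' @param X_env Matrix/data frame of environmental predictors (pre-screened,
#'   e.g. by [vif_screen()]).
#' @param adjusted Use adjusted R-squared? (default `TRUE`).
#' @return Object of class `varpart2`: tibble `fractions` (`fraction`,
#'   `value`), `r2` (named: spatial, env, both), `adjusted` flag, `n`.
#' @export
#' @examples
#' set.seed(1)
#' s <- matrix(rnorm(100), 50); e <- matrix(rnorm(100), 50)
#' partition_variation(s[, 1] + e[, 1] + rnorm(50), s, e)
partition_variation <- function(y, X_spatial, X_env, adjusted = TRUE) {
  Xs <- as.matrix(X_spatial)
  Xe <- as.matrix(X_env)
  n <- length(y)
  if (nrow(Xs) != n || nrow(Xe) != n)
    rl_abort("y, X_spatial and X_env must share row count", "contract_violation")
  if (n <= ncol(Xs) + ncol(Xe) + 1)
    rl_abort("n must exceed the combined number of predictors",
             "contract_violation")
  r2s <- r2_of(y, Xs, adjusted)
  r2e <- r2_of(y, Xe, adjusted)
  r2b <- r2_of(y, cbind(Xs, Xe), adjusted)
  fr <- tibble(
    fraction = c("pure_spatial", "pure_environmental", "shared", "residual"),
    value = c(r2b - r2e, r2b - r2s, r2s + r2e - r2b, 1 - r2b)
  )
  structure(list(fractions = fr,
                 r2 = c(spatial = r2s, env = r2e, both = r2b),
                 adjusted = adjusted, n = n),
            class = "varpart2")
}

#' @export
print.varpart2 <- function(x, ...) {
  cat("<varpart2> ", if (x$adjusted) "adjusted" else "raw",
      " R2; n = ", x$n, "\n", sep = "")
  print(x$fractions)
  invisible(x)
}

#' @export
tidy.varpart2 <- function(x, ...) x$fractions

#' @export
glance.varpart2 <- function(x, ...) {
  tibble(r2_spatial = x$r2[["spatial"]], r2_env = x$r2[["env"]],
         r2_both = x$r2[["both"]], adjusted = x$adjusted, n = x$n)
}

#' @export
autoplot.varpart2 <- function(object, ...) {
  dat <- object$fractions
  dat$fraction <- factor(dat$fraction, levels = dat$fraction)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL,
                  y = if (object$adjusted) "adjusted R² fraction"
                      else "R² fraction",
                  title = "Variation partitioning: spatial vs environmental") +
    ggplot2::theme_minimal()
}

# R2 of every predictor subset, indexed by bitmask + 1
subset_r2 <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    ix <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    out[mask + 1] <- r2_of(y, X[, ix, drop = FALSE])
  }
  out
}

#' Exact lmg hierarchical relative importance
#'
#' Decomposes the R-squared of the full linear model into per-predictor
#' shares: each predictor's share is its sequential R-squared increase
#' averaged over all p! orderings of model entry, computed exactly through
#' the subset reformulation (increments over all 2^p subsets weighted by
#' 1 / (p * C(p-1, |S|))). Shares are nonnegative for OLS and sum to the
#' full-model R-squared.
#'
#' @param y Numeric response.
#' @param X Data frame / matrix of predictors, p <= 10 for exact enumeration
#'   (beyond that, pass `sample_orderings` for a seeded Monte-Carlo average).
#' @param sample_orderings Number of random orderings to average when p > 10
#'   (`NULL` = exact only).
#' @param seed Seed for the sampled-orderings mode.
#' @return Object of class `lmg`: tibble `shares` with `predictor`, `share`
#'   (R-squared units), `pct` (share / R2 * 100), and `r2` (full model).
#' @export
#' @examples
#' X <- data.frame(a = rnorm(40), b = rnorm(40))
#' lmg_importance(X$a + 0.5 * X$b + rnorm(40), X)
lmg_importance <- function(y, X, sample_orderings = NULL, seed = NULL) {
  X <- as_tibble(X)
  p <- ncol(X)
  nm <- names(X)
  if (p > 10 && is.null(sample_orderings))
    rl_abort(paste("exact lmg enumerates 2^p subsets and is limited to",
                   "p <= 10; use sample_orderings for a seeded Monte-Carlo",
                   "average"), "contract_violation")
  Xm <- as.matrix(X)
  if (!is.null(sample_orderings)) {
    if (!is.null(seed)) set.seed(seed)
    shares <- numeric(p)
    for (b in seq_len(sample_orderings)) {
      ord <- sample.int(p)
      prev <- 0
      for (k in seq_len(p)) {
        r2k <- r2_of(y, Xm[, ord[seq_len(k)], drop = FALSE])
        shares[ord[k]] <- shares[ord[k]] + (r2k - prev)
        prev <- r2k
      }
    }
    shares <- shares / sample_orderings
    r2full <- r2_of(y, Xm)
  } else {
    r2 <- subset_r2(y, Xm)
    shares <- numeric(p)
    bits <- bitwShiftL(1L, seq_len(p) - 1L)
    for (j in seq_len(p)) {
      others <- setdiff(seq_len(p), j)
      o_bits <- bits[others]
      n_others <- p - 1L
      for (smask in 0:(2^n_others - 1L)) {
        ix <- which(bitwAnd(smask, bitwShiftL(1L, seq_len(n_others) - 1L)) != 0L)
        mask <- sum(o_bits[ix])
        k <- length(ix)
        w <- 1 / (p * choose(p - 1, k))
        shares[j] <- shares[j] +
          w * (r2[mask + bits[j] + 1] - r2[mask + 1])
      }
    }
    r2full <- r2[2^p]
  }
  structure(list(shares = tibble(predictor = nm, share = shares,
                                 pct = 100 * shares / r2full),
                 r2 = r2full),
            class = "lmg")
}

#' @export
print.lmg <- function(x, ...) {
  cat("<lmg> full-model R2 =", signif(x$r2, 4), "\n")
  print(x$shares)
  invisible(x)
}

#' @export
tidy.lmg <- function(x, ...) x$shares

#' @export
glance.lmg <- function(x, ...) tibble(r2 = x$r2)

#' @export
autoplot.lmg <- function(object, ...) {
  dat <- object$shares %>% arrange(.data$share)
  dat$predictor <- factor(dat$predictor, levels = dat$predictor)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$predictor, y = 100 * .data$share)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "share of variance (%)",
                  title = "lmg relative importance") +
    ggplot2::theme_minimal()
}

#' Despatialized relative importance of environmental predictors
#'
#' Removes the spatial (connectivity) signal by partial regression:
#' the response and every environmental predictor are residualized on the
#' selected spatial eigenfunctions, then [lmg_importance()] is run on the
#' residualized system. Shares are reported on two scales: as fractions of
#' the residual (despatialized) variance (`share_partial`, summing to the
#' partial R-squared) and as fractions of the total variance of y
#' (`share_total`, summing -- in raw-R2 mode -- to the pure environmental
#' Venn fraction of [partition_variation()]).
#'
#' @param y Numeric response.
#' @param X_spatial Selected spatial eigenfunctions (may have 0 columns, in
#'   which case the result reduces to [lmg_importance()]).
#' @param X_env Environmental predictor table.
#' @return Object of class `lmg_despatialized`: tibble `shares`
#'   (`predictor`, `share_partial`, `share_total`, `pct`), `r2_partial`,
#'   `pure_environmental`.
#' @export
despatialized_importance <- function(y, X_spatial, X_env) {
  Xs <- as.matrix(X_spatial)
  Xe <- as_tibble(X_env)
  if (ncol(Xs) > 0) {
    H <- cbind(1, Xs)
    resid_on <- function(v) lm.fit(H, v)$residuals
    y_res <- resid_on(y)
    if (sum(y_res^2) < 1e-12 * sum((y - mean(y))^2))
      rl_abort("spatial basis spans the response exactly: nothing left to partition",
               "degenerate_error")
    Xe_res <- as_tibble(as.data.frame(apply(as.matrix(Xe), 2, resid_on)))
  } else {
    y_res <- y
    Xe_res <- Xe
  }
  base <- lmg_importance(y_res, Xe_res)
  scale_fac <- sum((y_res - mean(y_res))^2) / sum((y - mean(y))^2)
  shares <- base$shares %>%
    rename(share_partial = "share") %>%
    mutate(share_total = .data$share_partial * scale_fac,
           pct = 100 * .data$share_partial / base$r2)
  structure(list(shares = shares, r2_partial = base$r2,
                 pure_environmental = base$r2 * scale_fac),
            class = "lmg_despatialized")
}

#' @export
print.lmg_despatialized <- function(x, ...) {
  cat("<lmg_despatialized> partial R2 =", signif(x$r2_partial, 4),
      "; pure environmental fraction =", signif(x$pure_environmental, 4), "\n")
  print(x$shares)
  invisible(x)
}

#' @export
tidy.lmg_despatialized <- function(x, ...) x$shares
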