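#' Sites-by-edges incidence matrix of a directional river graph
#'
#' Entry (i, j) equals the weight of edge j if edge j lies on a path from an
#' origin to site i, else 0. Virtual origin nodes contribute no rows. With
#' several origins the construction behaves as if a single super-origin fed
#' them through zero-influence bookkeeping edges: an edge (u -> v) influences
#' site i exactly when i equals v or is a downstream descendant of v, which on
#' a braided graph yields the union of the edges on all origin-to-site paths.
#'
#' @param graph A [river_graph()].
#' @return Numeric matrix, rows named by station id (graph order), columns by
#'   `parent->child` edge labels.
#' @export
#' @examples
#' g <- river_graph(data.frame(parent = c("o", "s1", "s2"),
#'                             child = c("s1", "s2", "s3")))
#' aem_incidence(g)
aem_incidence <- function(graph) {
  ig <- as_igraph(graph)
  sites <- station_ids(graph)
  edges <- graph$edges
  m <- matrix(0, nrow = length(sites), ncol = nrow(edges),
              dimnames = list(sites,
                              paste0(edges$parent, "->", edges$child)))
  for (j in seq_len(nrow(edges))) {
    v <- edges$child[j]
    downstream <- names(igraph::subcomponent(ig, v, mode = "out"))
    hit <- intersect(downstream, sites)
    m[hit, j] <- edges$weight[j]
  }
  m
}

#' Asymmetric eigenvector map basis
#'
#' Column-centers the sites-by-edges incidence matrix and takes its singular
#' value decomposition; the left singular vectors associated with positive
#' singular values are the AEM spatial eigenfunctions. Columns are centered,
#' orthonormal, and ordered by decreasing singular value; each column's sign
#' is fixed so its largest-magnitude element is positive, making the basis
#' deterministic across linear-algebra backends.
#'
#' @param incidence Matrix from [aem_incidence()] (or a [river_graph()],
#'   which is converted first).
#' @return Object of class `aem_basis`: `vectors` (sites x k matrix, columns
#'   `AEM1..AEMk`), `values` (positive singular values, descending),
#'   `incidence` (retained for diagnostics).
#' @export
aem_basis <- function(incidence) {
  if (inherits(incidence, "river_graph")) incidence <- aem_incidence(incidence)
  if (nrow(incidence) < 2)
    rl_abort("AEM basis needs at least 2 sites", "domain_error")
  mc <- scale(incidence, center = TRUE, scale = FALSE)
  sv <- svd(mc)
  tol <- max(dim(mc)) * .Machine$double.eps * max(sv$d, 0)
  keep <- which(sv$d > tol)
  if (length(keep) == 0) {
    warn("all sites share identical connectivity: empty AEM basis")
    vectors <- matrix(numeric(0), nrow = nrow(incidence), ncol = 0,
                      dimnames = list(rownames(incidence), NULL))
    values <- numeric(0)
  } else {
    vectors <- sv$u[, keep, drop = FALSE]
    values <- sv$d[keep]
    # deterministic sign: largest-magnitude element positive
    for (k in seq_len(ncol(vectors))) {
      i <- which.max(abs(vectors[, k]))
      if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
    }
    dimnames(vectors) <- list(rownames(incidence),
                              paste0("AEM", seq_along(keep)))
  }
  structure(list(vectors = vectors, values = values, incidence = incidence),
            class = "aem_basis")
}

#' @export
print.aem_basis <- function(x, ...) {
  cat("<aem_basis> ", nrow(x$vectors), " sites x ", ncol(x$vectors),
      " eigenfunctions\n", sep = "")
  invisible(x)
}

#' @export
tidy.aem_basis <- function(x, ...) {
  as_tibble(x$vectors, rownames = "station") %>%
    tidyr::pivot_longer(-"station", names_to = "eigenfunction",
                        values_to = "score")
}

#' Forward selection of AEM eigenfunctions against a response
#'
#' Greedy forward selection: at each step the remaining eigenfunction with
#' the largest gain in R-squared is tested with a seeded permutation test
#' whose statistic is that maximum gain (computed on the residuals of the
#' current model, so the test accounts for the selection over candidates);
#' the eigenfunction is retained while the permutation p-value is at most
#' `alpha` *and* the adjusted R-squared increases (double stopping rule).
#' Ties in gain are broken by singular-value order.
#'
#' @param basis An [aem_basis()].
#' @param response Numeric response, one value per site (basis row order).
#' @param alpha Significance level for the permutation test.
#' @param n_permutations Number of permutations.
#' @param seed Integer seed for the permutation draws (`NULL` = current RNG).
#' @return Object of class `aem_selection`: tibble `steps` (one row per
#'   retained eigenfunction: `eigenfunction`, `index`, `r2_gain`, `cum_r2`,
#'   `cum_adj_r2`, `p_value`) and integer vector `selected`.
#' @export
aem_forward_select <- function(basis, response, alpha = 0.05,
                               n_permutations = 999, seed = NULL) {
  U <- basis$vectors
  n <- nrow(U)
  if (length(response) != n)
    rl_abort("response length must equal the number of sites", "domain_error")
  if (!is.null(seed)) set.seed(seed)
  yc <- response - mean(response)
  ssy <- sum(yc^2)
  empty <- structure(list(steps = tibble(eigenfunction = character(),
                                         index = integer(),
                                         r2_gain = numeric(),
                                         cum_r2 = numeric(),
                                         cum_adj_r2 = numeric(),
                                         p_value = numeric()),
                          selected = integer(0)),
                     class = "aem_selection")
  if (ssy == 0 || ncol(U) == 0) return(empty)

  # columns are centered and orthonormal, so each candidate's R2 gain is
  # (u_j' y)^2 / ssy independently of the already-selected set
  scores2 <- drop(crossprod(U, yc))^2
  selected <- integer(0)
  steps <- list()
  adj <- function(r2, k) 1 - (1 - r2) * (n - 1) / (n - 1 - k)
  cum_ss <- 0
  adj_prev <- 0
  remaining <- seq_len(ncol(U))
  while (length(remaining) > 0 && length(selected) < n - 2) {
    j <- remaining[which.max(scores2[remaining])]
    r <- yc - U[, selected, drop = FALSE] %*%
      crossprod(U[, selected, drop = FALSE], yc)
    ss_r <- ssy - cum_ss
    if (ss_r <= 0) break
    obs <- scores2[j] / ss_r
    exceed <- 0L
    Urem <- U[, remaining, drop = FALSE]
    for (b in seq_len(n_permutations)) {
      rp <- r[sample.int(n)]
      stat <- max(drop(crossprod(Urem, rp - mean(rp)))^2) / ss_r
      if (stat >= obs) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_permutations + 1)
    new_cum <- cum_ss + scores2[j]
    adj_new <- adj(new_cum / ssy, length(selected) + 1L)
    if (p > alpha || adj_new <= adj_prev) break
    selected <- c(selected, j)
    steps[[length(steps) + 1L]] <- tibble(
      eigenfunction = colnames(U)[j], index = j,
      r2_gain = scores2[j] / ssy, cum_r2 = new_cum / ssy,
      cum_adj_r2 = adj_new, p_value = p)
    cum_ss <- new_cum
    adj_prev <- adj_new
    remaining <- setdiff(remaining, j)
  }
  structure(list(steps = bind_rows(steps), selected = selected),
            class = "aem_selection")
}

#' @export
print.aem_selection <- function(x, ...) {
  cat("<aem_selection> ", length(x$selected), " eigenfunctions retained\n",
      sep = "")
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

#' @export
tidy.aem_selection <- function(x, ...) x$steps

#' Matrix of the selected eigenfunctions
#'
#' @param basis An [aem_basis()].
#' @param selection An [aem_forward_select()] result (or integer indices).
#' @return Sites x selected matrix.
#' @export
aem_selected_matrix <- function(basis, selection) {
  idx <- if (inherits(selection, "aem_selection")) selection$selected else selection
  basis$vectors[, idx, drop = FALSE]
}
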