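#' Bray-Curtis dissimilarity matrix
#'
#' \deqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between sample
#' rows; 0 for identical compositions, 1 for disjoint supports. Accepts
#' counts or relative abundances. Empty samples are excluded with a
#' warning (their dissimilarity is undefined).
#'
#' @param m non-negative matrix, samples x taxa.
#' @return symmetric dissimilarity matrix with zero diagonal, attribute
#'   `excluded` listing dropped empty samples.
#' @export
bray_curtis <- function(m) {
  if (any(m < 0)) stop("negative abundances", call. = FALSE)
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty)) {
    warning("excluding empty samples from distances: ",
            paste(empty, collapse = ", "), call. = FALSE)
    m <- m[rowSums(m) > 0, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 non-empty samples", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <-
      sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  attr(d, "excluded") <- empty
  d
}

#' Effect-size band for an ANOSIM R statistic
#'
#' Interpretation bands for between-group separation: `R > 0.75` large,
#' `0.5 < R <= 0.75` medium, `0.25 < R <= 0.5` small, anything at or below
#' 0.25 negligible.
#'
#' @param R ANOSIM statistic in [-1, 1].
#' @return one of `"large"`, `"medium"`, `"small"`, `"negligible"`.
#' @export
anosim_band <- function(R) {
  stopifnot(R >= -1 - 1e-12, R <= 1 + 1e-12)
  if (R > 0.75) "large"
  else if (R > 0.5) "medium"
  else if (R > 0.25) "small"
  else "negligible"
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones. All pairwise dissimilarities are ranked (ties
#' get mean ranks) and
#' \deqn{R = (\bar r_B - \bar r_W) / (n(n-1)/4)}
#' compares the mean between-group and within-group ranks; R near 0 means
#' no separation, 1 complete separation. Significance comes from random
#' relabeling of samples, with the add-one correction
#' \eqn{p = (1 + \#\{R^* \ge R\}) / (1 + n_{perm})} so p is never zero.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param groups group label per sample (length n, >= 2 groups with >= 2
#'   samples each).
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed for the permutation stream.
#' @return list with elements `R`, `p`, `n_permutations`, `band`.
#' @export
anosim <- function(d, groups, n_perm = 999L, seed = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(ncol(d) == n, length(groups) == n)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)
  lower <- lower.tri(d)
  rk <- matrix(0, n, n)
  rk[lower] <- rank(d[lower])
  rk <- rk + t(rk)
  stat <- function(g) {
    between <- outer(g, g, "!=") & lower
    within <- outer(g, g, "==") & lower
    (mean(rk[between]) - mean(rk[within])) / (n * (n - 1) / 4)
  }
  R <- stat(groups)
  if (is.nan(R)) R <- 0  # all distances tied
  run <- function() {
    perm_R <- vapply(seq_len(n_perm), function(i) {
      r <- stat(sample(groups))
      if (is.nan(r)) 0 else r
    }, numeric(1L))
    (1 + sum(perm_R >= R)) / (1 + n_perm)
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  list(R = R, p = p, n_permutations = as.integer(n_perm),
       band = anosim_band(R))
}

#' Hierarchical-clustering leaf order for heatmap display
#'
#' Agglomerative clustering of the dissimilarity matrix (UPGMA/average
#' linkage by default); the returned leaf order is the tested artifact used
#' to arrange heatmap rows and columns.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param linkage agglomeration method passed to [stats::hclust].
#' @return list with `order` (sample ids in leaf order) and `tree`
#'   (the `hclust` object).
#' @export
cluster_order <- function(d, linkage = "average") {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  tree <- stats::hclust(d, method = linkage)
  list(order = tree$labels[tree$order], tree = tree)
}
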