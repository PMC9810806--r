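#' Correspondence analysis
#'
#' Eigen-decomposition of the chi-square standardized residual matrix
#' \deqn{Q_{ij} = (p_{ij} - r_i c_j) / \sqrt{r_i c_j}} of a non-negative
#' abundance matrix, via singular value decomposition. Total inertia is
#' \eqn{\sum Q^2}; eigenvalues are squared singular values.
#'
#' @param Y non-negative matrix (samples x taxa). All-zero rows/columns are
#'   dropped before analysis.
#' @return list with `eigenvalues` (descending, above numerical noise),
#'   `total_inertia`, `row_scores` and `col_scores` (standard coordinates,
#'   one column per axis), `row_mass`, `col_mass`.
#' @export
correspondence_analysis <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("negative abundances", call. = FALSE)
  Y <- Y[rowSums(Y) > 0, colSums(Y) > 0, drop = FALSE]
  if (nrow(Y) < 2L || ncol(Y) < 2L)
    stop("matrix has rank 0 after removing empty rows/columns",
         call. = FALSE)
  P <- Y / sum(Y)
  r <- rowSums(P)
  c <- colSums(P)
  Q <- (P - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(Q)
  keep <- sv$d^2 > max(sv$d^2, 0) * 1e-12 & sv$d^2 > 1e-14
  d <- sv$d[keep]
  list(eigenvalues = d^2,
       total_inertia = sum(Q^2),
       row_scores = sweep(sv$u[, keep, drop = FALSE], 1L, sqrt(r), "/"),
       col_scores = sweep(sv$v[, keep, drop = FALSE], 1L, sqrt(c), "/"),
       row_mass = r, col_mass = c,
       Q = Q)
}

#' DCA axis-1 gradient length
#'
#' Estimates the length of the first compositional gradient in standard
#' deviation (species turnover) units, the quantity used to choose between
#' linear (RDA) and unimodal (CCA) constrained ordination. Site scores come
#' from the first correspondence-analysis axis (reciprocal averaging);
#' nonlinear rescaling by segments then equalizes the mean within-species
#' dispersion of site scores ("tolerance") along the axis, so one unit of
#' the rescaled axis is one SD of species turnover, and the gradient length
#' is the range of rescaled site scores. The implementation follows the
#' segment-rescaling idea of detrended correspondence analysis (26
#' segments, 4 iterations by default); exact numerical agreement with
#' legacy DECORANA output is not claimed.
#'
#' @param Y non-negative matrix (samples x taxa), >= 3 samples.
#' @param n_segments number of axis segments for local tolerance estimates.
#' @param rescale_iter rescaling iterations.
#' @param threshold_low,threshold_high gradient-length cutoffs: below
#'   `threshold_low` the linear method (RDA) is chosen, above
#'   `threshold_high` the unimodal method (CCA); between them the default
#'   is CCA (unimodal is the safe choice in the ambiguous band).
#' @return list with `length` (SD units), `chosen_method` (`"RDA"` or
#'   `"CCA"`), and `site_scores` (rescaled axis-1 scores).
#' @export
dca_gradient_length <- function(Y, n_segments = 26L, rescale_iter = 4L,
                                threshold_low = 3, threshold_high = 4) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 3L) stop("need at least 3 samples", call. = FALSE)
  Y <- Y[rowSums(Y) > 0, colSums(Y) > 0, drop = FALSE]
  ca <- tryCatch(correspondence_analysis(Y), error = function(e) NULL)
  if (is.null(ca) || !length(ca$eigenvalues) ||
      ca$eigenvalues[[1L]] < 1e-10) {
    return(list(length = 0,
                chosen_method = choose_ordination_method(0, threshold_low,
                                                         threshold_high),
                site_scores = rep(0, nrow(Y))))
  }
  x <- ca$row_scores[, 1L]
  names(x) <- rownames(Y)
  for (iter in seq_len(rescale_iter)) {
    x <- rescale_axis(x, Y, n_segments)
  }
  len <- diff(range(x))
  list(length = len,
       chosen_method = choose_ordination_method(len, threshold_low,
                                                threshold_high),
       site_scores = x)
}

# one Hill-style rescaling pass: estimate local species tolerance per axis
# segment and stretch segments so tolerance ~= 1 everywhere
rescale_axis <- function(x, Y, n_segments) {
  col_tot <- colSums(Y)
  u <- colSums(Y * x) / col_tot                     # species optima
  tol2 <- colSums(Y * outer(x, u, "-")^2) / col_tot # species tolerance^2
  # species present in a single sample carry no dispersion information
  informative <- colSums(Y > 0) >= 2L & tol2 > 0
  if (!any(informative)) return(x)
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) return(x)
  breaks <- seq(lo, hi, length.out = n_segments + 1L)
  seg_of <- function(v) pmin(pmax(findInterval(v, breaks,
                                               rightmost.closed = TRUE), 1L),
                             n_segments)
  seg_u <- seg_of(u[informative])
  wt <- col_tot[informative]
  v_s <- vapply(seq_len(n_segments), function(s) {
    in_s <- seg_u == s
    if (any(in_s)) sum(wt[in_s] * tol2[informative][in_s]) / sum(wt[in_s])
    else NA_real_
  }, numeric(1L))
  overall <- sum(wt * tol2[informative]) / sum(wt)
  v_s[is.na(v_s)] <- overall
  # clamp extreme local estimates: a near-zero tolerance in one sparse
  # segment must not blow the axis up
  v_s <- pmin(pmax(v_s, overall / 25), overall * 25)
  old_w <- diff(breaks)
  new_w <- old_w / sqrt(v_s)          # dL' = dL / tolerance
  new_breaks <- c(0, cumsum(new_w))
  seg_x <- seg_of(x)
  new_breaks[seg_x] + (x - breaks[seg_x]) / old_w[seg_x] * new_w[seg_x]
}

#' Choose the constrained-ordination model from a DCA gradient length
#'
#' Longest gradient above `threshold_high` SD units: unimodal responses are
#' expected and CCA applies; below `threshold_low`: linear responses and
#' RDA. In the ambiguous band the unimodal method is the default.
#'
#' @param length gradient length in SD units (>= 0).
#' @param threshold_low RDA cutoff (default 3).
#' @param threshold_high CCA cutoff (default 4).
#' @param midband method used between the cutoffs (default `"CCA"`).
#' @return `"RDA"` or `"CCA"`.
#' @export
choose_ordination_method <- function(length, threshold_low = 3,
                                     threshold_high = 4, midband = "CCA") {
  stopifnot(length >= 0, threshold_low <= threshold_high)
  if (length > threshold_high) "CCA"
  else if (length < threshold_low) "RDA"
  else match.arg(midband, c("CCA", "RDA"))
}

# drop linearly dependent columns (after centering/weighting), keeping the
# first of each dependent set; returns kept column indices
nonaliased_columns <- function(X, tol = 1e-8) {
  qrX <- qr(X, tol = tol)
  sort(qrX$pivot[seq_len(qrX$rank)])
}

#' Redundancy analysis (RDA)
#'
#' Linear constrained ordination: species columns are centered (optionally
#' scaled), environmental columns z-scored (units differ), the community
#' matrix is projected onto the column space of the constraints, and the
#' fitted values are eigen-decomposed. Inertia is variance
#' (sum of squares / (n - 1)).
#'
#' @param Y samples x taxa abundance matrix.
#' @param X samples x variables environmental matrix (complete rows).
#' @param standardize z-score environmental columns (default TRUE).
#' @param scale_species also scale species columns to unit variance
#'   (default FALSE).
#' @return object of class `ordination_result`: `method`, `eigenvalues`
#'   (constrained, descending), `total_inertia`, `constrained_inertia`,
#'   `site_scores` (weighted-average), `site_scores_lc` (fitted),
#'   `species_scores`, `biplot_scores` (correlations of env variables with
#'   fitted site scores), `axis_explained` (fraction of total inertia per
#'   constrained axis), `axis_explained_constrained` (fraction of the
#'   constrained inertia), `cum_explained_2axes` (first two constrained
#'   axes as a fraction of the species-environment (constrained)
#'   variability), `aliased` (dropped collinear variables).
#' @export
rda <- function(Y, X, standardize = TRUE, scale_species = FALSE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  if (anyNA(X)) stop("environmental matrix has missing values", call. = FALSE)
  Yc <- scale(Y, center = TRUE, scale = scale_species)
  Yc[is.nan(Yc)] <- 0
  Xc <- scale(X, center = TRUE, scale = standardize)
  Xc[, apply(X, 2L, function(v) length(unique(v)) == 1L)] <- 0
  keep <- nonaliased_columns(Xc)
  aliased <- setdiff(colnames(X), colnames(X)[keep])
  if (length(aliased))
    warning("dropping collinear constraints: ",
            paste(aliased, collapse = ", "), call. = FALSE)
  Xc <- Xc[, keep, drop = FALSE]
  if (ncol(Xc) >= n)
    stop("need more samples than constraint variables", call. = FALSE)
  qrX <- qr(Xc)
  Yfit <- qr.fitted(qrX, Yc)
  sv <- svd(Yfit)
  pos <- sv$d^2 > max(sv$d^2, 1e-300) * 1e-12 & sv$d^2 > 1e-14
  d <- sv$d[pos]
  eig <- d^2 / (n - 1)
  total <- sum(Yc^2) / (n - 1)
  constrained <- sum(Yfit^2) / (n - 1)
  V <- sv$v[, pos, drop = FALSE]
  rownames(V) <- colnames(Y)
  site_wa <- Yc %*% V
  site_lc <- Yfit %*% V
  rownames(site_wa) <- rownames(site_lc) <- rownames(Y)
  biplot <- if (ncol(Xc) && length(d))
    stats::cor(Xc, site_lc) else NULL
  structure(list(method = "RDA", eigenvalues = eig,
                 total_inertia = total, constrained_inertia = constrained,
                 site_scores = site_wa, site_scores_lc = site_lc,
                 species_scores = V, biplot_scores = biplot,
                 axis_explained = eig / total,
                 axis_explained_constrained =
                   if (constrained > 0) eig / constrained else eig * 0,
                 cum_explained_2axes =
                   if (constrained > 0)
                     sum(eig[seq_len(min(2L, length(eig)))]) / constrained
                   else 0,
                 aliased = aliased),
            class = "ordination_result")
}

#' Canonical correspondence analysis (CCA)
#'
#' Unimodal constrained ordination: the chi-square standardized residual
#' matrix of the community table is regressed, with row-mass weights, on
#' the standardized environmental variables, and the fitted component is
#' eigen-decomposed. With a full set of free constraints CCA reproduces
#' plain correspondence analysis.
#'
#' @inheritParams rda
#' @return `ordination_result` as for [rda]; species scores use scaling-2
#'   (scaled by singular values), site scores are weighted averages.
#' @export
cca <- function(Y, X, standardize = TRUE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(Y))
  if (anyNA(X)) stop("environmental matrix has missing values", call. = FALSE)
  keep_r <- rowSums(Y) > 0
  keep_c <- colSums(Y) > 0
  Y <- Y[keep_r, keep_c, drop = FALSE]
  X <- X[keep_r, , drop = FALSE]
  n <- nrow(Y)
  ca <- correspondence_analysis(Y)
  Q <- ca$Q
  r <- ca$row_mass
  Xw <- weighted_constraints(X, r, standardize)
  aliased <- attr(Xw, "aliased")
  if (length(aliased))
    warning("dropping collinear constraints: ",
            paste(aliased, collapse = ", "), call. = FALSE)
  if (ncol(Xw) == 0L) {
    Qfit <- Q * 0
  } else {
    qrX <- qr(Xw)
    Qfit <- qr.fitted(qrX, Q)
  }
  sv <- svd(Qfit)
  pos <- sv$d^2 > max(sv$d^2, 1e-300) * 1e-12 & sv$d^2 > 1e-14
  d <- sv$d[pos]
  eig <- d^2
  total <- ca$total_inertia
  constrained <- sum(Qfit^2)
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  site <- sweep(U, 1L, sqrt(r), "/")
  species <- sweep(sweep(V, 1L, sqrt(ca$col_mass), "/"), 2L, d, "*")
  rownames(site) <- rownames(Y)
  rownames(species) <- colnames(Y)
  site_lc <- site
  biplot <- if (ncol(Xw) && length(d)) {
    bp <- crossprod(Xw, U)  # weighted correlation with axes
    sw <- sqrt(colSums(Xw^2))
    sweep(bp, 1L, pmax(sw, 1e-12), "/")
  } else NULL
  structure(list(method = "CCA", eigenvalues = eig,
                 total_inertia = total, constrained_inertia = constrained,
                 site_scores = site, site_scores_lc = site_lc,
                 species_scores = species, biplot_scores = biplot,
                 axis_explained = eig / total,
                 axis_explained_constrained =
                   if (constrained > 0) eig / constrained else eig * 0,
                 cum_explained_2axes =
                   if (constrained > 0)
                     sum(eig[seq_len(min(2L, length(eig)))]) / constrained
                   else 0,
                 aliased = aliased),
            class = "ordination_result")
}

# row-mass weighted, centered, optionally standardized constraint matrix
# in the sqrt(r)-weighted space used by CCA
weighted_constraints <- function(X, r, standardize = TRUE) {
  mu <- colSums(X * r)
  Xc <- sweep(X, 2L, mu)
  if (standardize) {
    sdw <- sqrt(colSums(Xc^2 * r))
    const <- sdw < 1e-12
    sdw[const] <- 1
    Xc <- sweep(Xc, 2L, sdw, "/")
    Xc[, const] <- 0
  }
  Xw <- Xc * sqrt(r)
  nz <- colSums(Xw^2) > 1e-20
  keep <- which(nz)[nonaliased_columns(Xw[, nz, drop = FALSE], tol = 1e-8)]
  out <- Xw[, keep, drop = FALSE]
  attr(out, "aliased") <- setdiff(colnames(X), colnames(X)[keep])
  out
}

#' Forward selection of environmental variables by permutation tests
#'
#' Greedy forward selection for constrained ordination: at each step the
#' candidate adding the most constrained inertia joins the model, and its
#' contribution is tested with a Monte-Carlo permutation pseudo-F test.
#' The default permutation scheme permutes the residuals of the current
#' reduced model (ter Braak style); simple row permutation of the response
#' is available via `permute = "rows"`. Selection stops when the best
#' candidate's permutation p-value exceeds `alpha` (or candidates run out).
#'
#' @param Y samples x taxa abundance matrix.
#' @param X samples x candidate-variables matrix.
#' @param method `"rda"` or `"cca"` (working response is the centered
#'   species matrix or the chi-square standardized residual matrix).
#' @param alpha stopping significance level (default 0.05).
#' @param n_perm permutations per test (default 999).
#' @param seed optional seed for the permutation stream.
#' @param permute `"residual"` (reduced-model residuals) or `"rows"`.
#' @return list with `selected` (variable names in selection order),
#'   `trace` (data.frame: step, variable, added_inertia, pseudo_F,
#'   p_value, selected flag) and `stopping` (reason the loop ended).
#' @export
forward_select <- function(Y, X, method = c("rda", "cca"), alpha = 0.05,
                           n_perm = 999L, seed = NULL,
                           permute = c("residual", "rows")) {
  method <- match.arg(method)
  permute <- match.arg(permute)
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 candidate variables", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  Y <- as.matrix(Y)
  keep_r <- rowSums(abs(Y)) > 0
  if (method == "cca") {
    Y <- Y[keep_r, colSums(Y) > 0, drop = FALSE]
    X <- X[keep_r, , drop = FALSE]
    ca <- correspondence_analysis(Y)
    W <- ca$Q
    C <- weighted_constraints(X, ca$row_mass, TRUE)
  } else {
    W <- scale(Y, center = TRUE, scale = FALSE)
    C <- scale(X, center = TRUE, scale = TRUE)
    C[, apply(X, 2L, function(v) length(unique(v)) == 1L)] <- 0
    attr(C, "aliased") <- character()
  }
  run <- function() forward_select_engine(W, C, alpha, n_perm, permute)
  if (is.null(seed)) run() else with_seed(seed, run())
}

forward_select_engine <- function(W, C, alpha, n_perm, permute) {
  n <- nrow(W)
  vars <- colnames(C)
  inertia <- function(Wm, cols) {
    if (!length(cols)) return(0)
    sum(qr.fitted(qr(C[, cols, drop = FALSE]), Wm)^2)
  }
  selected <- character()
  trace <- list()
  stopping <- "no candidates remaining"
  step <- 0L
  repeat {
    cand <- setdiff(vars, selected)
    if (!length(cand)) break
    base_in <- inertia(W, selected)
    added <- vapply(cand, function(v)
      inertia(W, c(selected, v)) - base_in, numeric(1L))
    added[added < 0] <- 0
    best <- cand[[which.max(added)]]
    if (added[[best]] <= 1e-12) {
      stopping <- "no candidate adds inertia"
      break
    }
    step <- step + 1L
    df_res <- n - 1L - length(selected) - 1L
    if (df_res < 1L) {
      stopping <- "residual degrees of freedom exhausted"
      break
    }
    f_of <- function(Wm) {
      i_red <- inertia(Wm, selected)
      i_full <- inertia(Wm, c(selected, best))
      num <- i_full - i_red
      den <- (sum(Wm^2) - i_full) / df_res
      if (den <= 1e-300) Inf else num / den
    }
    f_obs <- f_of(W)
    if (permute == "residual" && length(selected)) {
      fit_red <- qr.fitted(qr(C[, selected, drop = FALSE]), W)
      res_red <- W - fit_red
    } else {
      fit_red <- matrix(0, n, ncol(W))
      res_red <- W
    }
    f_perm <- vapply(seq_len(n_perm), function(b)
      f_of(fit_red + res_red[sample.int(n), , drop = FALSE]), numeric(1L))
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    sel <- p <= alpha
    trace[[step]] <- data.frame(step = step, variable = best,
                                added_inertia = added[[best]],
                                pseudo_F = f_obs, p_value = p,
                                selected = sel, stringsAsFactors = FALSE)
    if (!sel) {
      stopping <- sprintf("best candidate '%s' not significant (p = %.4g > %g)",
                          best, p, alpha)
      break
    }
    selected <- c(selected, best)
    stopping <- "all candidates selected"
  }
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(), variable = character(),
                    added_inertia = numeric(), pseudo_F = numeric(),
                    p_value = numeric(), selected = logical()),
       stopping = stopping)
}
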