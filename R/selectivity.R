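#' Ivlev electivity index
#'
#' \deqn{E = (r_i - p_i)/(r_i + p_i)} where \eqn{r_i} is the taxon's
#' relative abundance in the diet and \eqn{p_i} its relative abundance in
#' the ambient water. +1 is exclusive preference (eaten, never available),
#' -1 complete avoidance (available, never eaten). When the taxon is absent
#' from both pools the index is defined as 0 by default (a taxon the
#' consumer never encountered expresses no selection); `NaN` is available
#' for callers who prefer to propagate missingness.
#'
#' @param ri diet relative abundance in [0, 1] (vectorised).
#' @param pi ambient relative abundance in [0, 1] (vectorised).
#' @param zero_zero value returned where `ri == pi == 0` (default 0).
#' @return electivity in [-1, 1].
#' @export
electivity <- function(ri, pi, zero_zero = 0) {
  if (any(ri < 0) || any(pi < 0))
    stop("relative abundances must be non-negative", call. = FALSE)
  if (any(ri > 1) || any(pi > 1))
    stop("relative abundances must not exceed 1", call. = FALSE)
  out <- (ri - pi) / (ri + pi)
  out[ri == 0 & pi == 0] <- zero_zero
  out
}

#' Classify electivity values into feeding-selectivity categories
#'
#' Strict thresholds: `E > +threshold` is `"preference"`,
#' `E < -threshold` is `"discrimination"`, the closed interval between is
#' `"non-selective"` (so a value exactly at the threshold is not selective).
#'
#' @param E electivity values in [-1, 1] (NA passed through).
#' @param threshold positive cutoff (default 0.25).
#' @return character vector of classifications.
#' @export
classify_electivity <- function(E, threshold = 0.25) {
  stopifnot(threshold > 0)
  ok <- is.na(E) | (E >= -1 - 1e-12 & E <= 1 + 1e-12)
  if (!all(ok))
    stop("electivity outside [-1, 1]: ", paste(E[!ok], collapse = ", "),
         call. = FALSE)
  out <- rep(NA_character_, length(E))
  out[!is.na(E)] <- "non-selective"
  out[!is.na(E) & E > threshold] <- "preference"
  out[!is.na(E) & E < -threshold] <- "discrimination"
  out
}

#' Seasonal electivity table (diet vs ambient water)
#'
#' For each season, reads are pooled across that season's samples within
#' each compartment (sites summed), giving one diet share `ri` and one
#' ambient share `pi` per taxon per season, from which E and its
#' classification are computed. Per-site electivity with averaging across
#' sites is available via `pooling = "site_mean"`. The gut table must
#' already have consumer self-reads removed.
#'
#' @param gut consumer-removed count matrix (samples x taxa), typically
#'   aggregated at class level with [aggregate_by_rank].
#' @param water ambient count matrix on the same taxon level (taxon sets
#'   may differ; the union is used).
#' @param meta sample frame covering all samples in both tables.
#' @param pooling `"sum"` (pool reads across sites; default) or
#'   `"site_mean"` (E per site, then averaged over sites with data).
#' @param threshold classification cutoff passed to [classify_electivity].
#' @return data.frame with columns `taxon`, `season`, `ri`, `pi`, `E`,
#'   `classification`. Seasons whose gut samples are all empty yield NA
#'   records rather than fabricated values.
#' @export
electivity_table <- function(gut, water, meta, pooling = c("sum", "site_mean"),
                             threshold = 0.25) {
  pooling <- match.arg(pooling)
  taxa <- union(colnames(gut), colnames(water))
  fill <- function(tab) {
    out <- matrix(0, nrow(tab), length(taxa),
                  dimnames = list(rownames(tab), taxa))
    out[, colnames(tab)] <- tab
    out
  }
  g <- fill(gut)
  w <- fill(water)
  season_of <- function(ids) meta$season[match(ids, meta$sample_id)]
  site_of <- function(ids) meta$site[match(ids, meta$sample_id)]
  res <- lapply(SEASONS, function(s) {
    gs <- g[season_of(rownames(g)) == s, , drop = FALSE]
    ws <- w[season_of(rownames(w)) == s, , drop = FALSE]
    if (!nrow(gs) || !nrow(ws)) return(NULL)
    if (pooling == "sum") {
      gt <- colSums(gs); wt <- colSums(ws)
      if (sum(gt) == 0 || sum(wt) == 0) {
        ri <- pi <- E <- rep(NA_real_, length(taxa))
      } else {
        ri <- gt / sum(gt)
        pi <- wt / sum(wt)
        E <- electivity(ri, pi)
      }
    } else {
      per_site <- lapply(unique(site_of(rownames(gs))), function(st) {
        gi <- colSums(gs[site_of(rownames(gs)) == st, , drop = FALSE])
        wi <- colSums(ws[site_of(rownames(ws)) == st, , drop = FALSE])
        if (sum(gi) == 0 || sum(wi) == 0) return(NULL)
        list(ri = gi / sum(gi), pi = wi / sum(wi))
      })
      per_site <- Filter(Negate(is.null), per_site)
      if (!length(per_site)) {
        ri <- pi <- E <- rep(NA_real_, length(taxa))
      } else {
        ri <- rowMeans(sapply(per_site, `[[`, "ri"))
        pi <- rowMeans(sapply(per_site, `[[`, "pi"))
        E <- rowMeans(sapply(per_site, function(x)
          electivity(x$ri, x$pi)))
      }
    }
    data.frame(taxon = taxa, season = s, ri = unname(ri), pi = unname(pi),
               E = unname(E),
               classification = classify_electivity(E, threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' McNaughton dominance index
#'
#' \deqn{Y_i = (n_i / N) \cdot f_i} — a taxon's overall read share times the
#' fraction of samples it occurs in, so a ubiquitous dominant's Y equals its
#' share while a patchy taxon is discounted. Computed on the ambient-water
#' community; the abundance share is read-weighted when counts are supplied
#' and sample-averaged when proportions are supplied.
#'
#' @param table count matrix or relative-abundance matrix (samples x taxa);
#'   empty samples (zero rows) are excluded.
#' @return data.frame with columns `taxon` and `Y`, sorted by decreasing Y.
#' @export
dominance_index <- function(table) {
  keep <- rowSums(table) > 0
  if (!any(keep)) stop("no non-empty samples", call. = FALSE)
  tab <- table[keep, , drop = FALSE]
  is_counts <- all(tab == round(tab)) && any(tab > 1)
  share <- if (is_counts) colSums(tab) / sum(tab)
           else colMeans(tab / rowSums(tab))
  occupancy <- colMeans(tab > 0)
  out <- data.frame(taxon = colnames(tab), Y = unname(share * occupancy),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$Y), ]
  rownames(out) <- NULL
  out
}

#' Per-taxon gut-versus-water differential abundance
#'
#' Two-sided Wilcoxon rank-sum tests on per-sample relative abundances,
#' taxon by taxon, with Benjamini-Hochberg control of the false discovery
#' rate. The exact permutation null is used whenever the data permit
#' (untied, small samples); otherwise the normal approximation with tie and
#' continuity correction applies. Taxa absent from every sample get p = 1
#' by convention. Empty samples (flagged by [relative_abundance]) are
#' dropped before testing.
#'
#' @param gut_rel relative-abundance matrix of gut samples.
#' @param water_rel relative-abundance matrix of water samples, same taxon
#'   level (taxon union used; missing columns treated as zero).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return data.frame with columns `taxon`, `mean_rel_gut`,
#'   `mean_rel_water`, `statistic`, `p_raw`, `q_fdr`, `significant`
#'   (q_fdr <= alpha) and `significant_raw` (p_raw <= alpha, as some
#'   figure conventions use unadjusted p).
#' @export
differential_enrichment <- function(gut_rel, water_rel, alpha = 0.05) {
  drop_empty <- function(m) {
    empty <- attr(m, "empty_samples")
    if (length(empty)) m <- m[!rownames(m) %in% empty, , drop = FALSE]
    m
  }
  g <- drop_empty(gut_rel)
  w <- drop_empty(water_rel)
  if (nrow(g) < 2L || nrow(w) < 2L)
    stop("need at least 2 non-empty samples per compartment", call. = FALSE)
  taxa <- union(colnames(g), colnames(w))
  col_or_zero <- function(m, t)
    if (t %in% colnames(m)) m[, t] else rep(0, nrow(m))
  res <- lapply(taxa, function(t) {
    x <- col_or_zero(g, t)
    y <- col_or_zero(w, t)
    if (all(x == 0) && all(y == 0)) {
      stat <- length(x) * length(y) / 2
      p <- 1
    } else if (all(x == x[[1L]]) && all(y == x[[1L]])) {
      stat <- length(x) * length(y) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                                correct = TRUE))
      stat <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(taxon = t, mean_rel_gut = mean(x), mean_rel_water = mean(y),
               statistic = stat, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$q_fdr <= alpha
  out$significant_raw <- out$p_raw <= alpha
  out[order(out$q_fdr, out$p_raw), ]
}
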