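#' Remove the consumer's own reads from a gut-content table
#'
#' Gut-content metabarcoding libraries are dominated by the consumer's own
#' sequences; these are subtracted before any diet composition is computed.
#' Matching is by lineage name at a chosen rank (default: genus, e.g.
#' `"Polyarthra"`). Samples left with zero reads are retained but flagged,
#' and are excluded from proportion-based statistics downstream.
#'
#' @param table validated OTU table (samples x OTUs).
#' @param tax taxonomy data.frame covering the table's OTUs.
#' @param consumer taxon name to remove.
#' @param rank rank at which `consumer` is matched (one of [TAX_RANKS]).
#' @return OTU table without the consumer's OTU columns, with attributes
#'   `removed_reads` (named per-sample tally) and `empty_samples`
#'   (ids of samples left with no reads).
#' @export
remove_consumer_reads <- function(table, tax, consumer = "Polyarthra",
                                  rank = "genus") {
  table <- validate_otu_table(table)
  rank <- match.arg(rank, TAX_RANKS)
  hit <- lineage_at(tax, colnames(table), rank) == consumer
  removed <- if (any(hit)) {
    rowSums(table[, hit, drop = FALSE])
  } else {
    stats::setNames(rep(0L, nrow(table)), rownames(table))
  }
  out <- table[, !hit, drop = FALSE]
  if (ncol(out) == 0L)
    stop("consumer removal dropped every OTU", call. = FALSE)
  empty <- rownames(out)[rowSums(out) == 0L]
  if (length(empty))
    warning("samples left empty after consumer removal: ",
            paste(empty, collapse = ", "), call. = FALSE)
  attr(out, "removed_reads") <- removed
  attr(out, "empty_samples") <- empty
  out
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Counts are summed over OTUs sharing a name at `rank`. OTUs unassigned at
#' `rank` are pooled into `"unclassified <deepest assigned ancestor>"`
#' buckets (e.g. `"unclassified Chlorophyta"`), so reads are conserved
#' exactly: per-sample totals of the output equal those of the input.
#'
#' @param table validated OTU table.
#' @param tax taxonomy data.frame.
#' @param rank target rank (one of [TAX_RANKS]).
#' @return count matrix, samples x taxa-at-rank.
#' @export
aggregate_by_rank <- function(table, tax, rank = "class") {
  table <- validate_otu_table(table)
  rank <- match.arg(rank, TAX_RANKS)
  labels <- rank_labels(tax, colnames(table), rank)
  groups <- factor(labels, levels = unique(labels))
  out <- t(rowsum(t(table), groups))
  out <- matrix(as.integer(out), nrow(out), ncol(out), dimnames = dimnames(out))
  validate_otu_table(out)
}

# label of each OTU at `rank`, with unclassified pooling
rank_labels <- function(tax, otu_ids, rank) {
  ri <- match(rank, TAX_RANKS)
  name <- lineage_at(tax, otu_ids, rank)
  need_bucket <- name == UNASSIGNED
  if (any(need_bucket)) {
    above <- TAX_RANKS[seq_len(ri - 1L)]
    anc <- rep("unclassified", sum(need_bucket))
    if (length(above)) {
      lin <- do.call(cbind, lapply(above, function(r)
        lineage_at(tax, otu_ids[need_bucket], r)))
      deepest <- apply(lin, 1L, function(p) {
        assigned <- p[p != UNASSIGNED]
        if (length(assigned)) assigned[[length(assigned)]] else NA_character_
      })
      anc <- ifelse(is.na(deepest), "unclassified",
                    paste("unclassified", deepest))
    }
    name[need_bucket] <- anc
  }
  name
}

#' Convert counts to per-sample relative abundances
#'
#' Each non-empty row is divided by its total. Empty rows (zero reads) are
#' kept as zero but flagged in the `empty_samples` attribute and must be
#' excluded from proportion-based statistics.
#'
#' @param table validated OTU table (or any non-negative count matrix).
#' @return numeric matrix of proportions with attribute `empty_samples`.
#' @export
relative_abundance <- function(table) {
  table <- validate_otu_table(table)
  tot <- rowSums(table)
  out <- matrix(0, nrow(table), ncol(table), dimnames = dimnames(table))
  nz <- tot > 0L
  out[nz, ] <- table[nz, , drop = FALSE] / tot[nz]
  attr(out, "empty_samples") <- rownames(table)[!nz]
  out
}

#' Exact rarefaction curve for one sample
#'
#' Expected OTU richness in a uniform random subsample of `n` reads drawn
#' without replacement, computed with the hypergeometric closed form
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N - N_i}{n} \big/ \binom{N}{n}\right]}
#' where \eqn{N_i} is OTU i's read count and \eqn{N} the sample total.
#' Binomial coefficients are evaluated in log-gamma arithmetic so the curve
#' is exact at sequencing-scale depths.
#'
#' @param counts named non-negative integer vector of per-OTU reads for one
#'   sample (zeros allowed; they do not contribute).
#' @param depths increasing subsample sizes, each between 1 and `sum(counts)`.
#' @return data.frame with columns `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  n_total <- sum(counts)
  depths <- as.integer(sort(unique(depths)))
  if (any(depths < 1L) || any(depths > n_total))
    stop("depths must lie in [1, ", n_total, "]", call. = FALSE)
  ni <- counts[counts > 0]
  er <- vapply(depths, function(n) {
    # P(OTU i absent from subsample) = C(N - Ni, n) / C(N, n)
    lp <- lchoose(n_total - ni, n) - lchoose(n_total, n)
    sum(1 - exp(lp))
  }, numeric(1L))
  data.frame(depth = depths, expected_richness = er)
}

#' Rarefaction curves for every sample in a table
#'
#' @param table validated OTU table.
#' @param n_points number of evenly spaced depths per sample (capped at the
#'   sample total); the sample's full depth is always included so the curve
#'   ends at the observed richness.
#' @return data.frame with columns `sample_id`, `depth`, `expected_richness`.
#' @export
rarefaction_curves <- function(table, n_points = 20L) {
  table <- validate_otu_table(table)
  out <- lapply(rownames(table), function(s) {
    tot <- sum(table[s, ])
    if (tot == 0L) return(NULL)
    depths <- unique(c(pmax(1L, round(seq(1L, tot,
                                          length.out = min(n_points, tot)))),
                       tot))
    cbind(sample_id = s, rarefaction_curve(table[s, ], depths))
  })
  do.call(rbind, out)
}

#' Shared and unique OTUs between two sample groups
#'
#' An OTU is "present" in a group when its reads summed over the group's
#' samples reach `detection_min` (default 1 read). The three returned sets
#' partition all OTUs observed in either group.
#'
#' @param table_a,table_b OTU tables for the two groups (the same OTU
#'   universe is not required; ids are matched by name).
#' @param detection_min minimum summed reads to count as present.
#' @return list with character-vector elements `shared`, `unique_a`,
#'   `unique_b` and integer `n_shared`, `n_unique_a`, `n_unique_b`.
#' @export
shared_unique <- function(table_a, table_b, detection_min = 1L) {
  stopifnot(detection_min >= 1L)
  present <- function(tab) {
    tot <- colSums(tab)
    names(tot)[tot >= detection_min]
  }
  a <- present(validate_otu_table(table_a))
  b <- present(validate_otu_table(table_b))
  out <- list(shared = sort(intersect(a, b)),
              unique_a = sort(setdiff(a, b)),
              unique_b = sort(setdiff(b, a)))
  out$n_shared <- length(out$shared)
  out$n_unique_a <- length(out$unique_a)
  out$n_unique_b <- length(out$unique_b)
  out
}
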