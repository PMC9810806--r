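#' Run the full diet-selectivity workflow
#'
#' Chains the analysis stages on paired gut/water OTU tables: consumer
#' self-read removal, class-level aggregation and relative abundance,
#' rarefaction curves, shared/unique OTU accounting, dominance and seasonal
#' electivity (the headline selectivity table), per-taxon gut-vs-water
#' Wilcoxon + FDR enrichment, Bray-Curtis + ANOSIM + clustering order, and
#' environmentally constrained ordination of the water community (DCA
#' gradient length decides RDA vs CCA; forward selection picks the
#' environmental drivers). The gut community's gradient length is also
#' reported, mirroring the per-compartment model choice.
#'
#' @param gut,water OTU count tables (samples x OTUs).
#' @param taxonomy taxonomy data.frame covering both tables.
#' @param meta sample frame covering all samples; water rows carry the
#'   environmental variables.
#' @param consumer,consumer_rank taxon removed from gut libraries.
#' @param rank aggregation rank for the composition analyses.
#' @param e_threshold electivity classification cutoff.
#' @param fdr_alpha FDR threshold for enrichment.
#' @param n_perm permutations for ANOSIM and forward selection.
#' @param seed seed for all permutation streams.
#' @param out_dir optional directory; when given, every table is written as
#'   TSV plus a JSON-like run report `report.txt` and `MANIFEST`.
#' @return list with elements `consumer_removal`, `rarefaction`, `venn`,
#'   `dominance`, `electivity`, `selectivity_table` (wide, one row per
#'   taxon with Y and per-season E), `enrichment`, `distance`, `anosim`,
#'   `cluster`, `gradient` (per compartment), `ordination`,
#'   `forward_selection`, `report`.
#' @export
run_pipeline <- function(gut, water, taxonomy, meta,
                         consumer = "Polyarthra", consumer_rank = "genus",
                         rank = "class", e_threshold = 0.25,
                         fdr_alpha = 0.05, n_perm = 999L, seed = 1L,
                         out_dir = NULL) {
  gut <- validate_otu_table(gut)
  water <- validate_otu_table(water)
  meta <- validate_sample_frame(meta)
  done <- character()
  res <- list()

  gut_clean <- remove_consumer_reads(gut, taxonomy, consumer, consumer_rank)
  res$consumer_removal <- list(
    removed_reads = attr(gut_clean, "removed_reads"),
    empty_samples = attr(gut_clean, "empty_samples"))
  done <- c(done, "consumer_removal")

  res$rarefaction <- rbind(
    cbind(compartment = "gut", rarefaction_curves(gut_clean)),
    cbind(compartment = "water", rarefaction_curves(water)))
  done <- c(done, "rarefaction")

  res$venn <- shared_unique(gut_clean, water)
  done <- c(done, "venn")

  gut_rank <- aggregate_by_rank(gut_clean, taxonomy, rank)
  water_rank <- aggregate_by_rank(water, taxonomy, rank)
  gut_rel <- relative_abundance(gut_rank)
  water_rel <- relative_abundance(water_rank)

  res$dominance <- dominance_index(water_rank)
  res$electivity <- electivity_table(gut_rank, water_rank, meta,
                                     threshold = e_threshold)
  res$selectivity_table <- selectivity_wide(res$electivity, res$dominance)
  done <- c(done, "selectivity")

  res$enrichment <- differential_enrichment(gut_rel, water_rel,
                                            alpha = fdr_alpha)
  done <- c(done, "enrichment")

  both_rel <- merge_compositions(gut_rel, water_rel)
  nonempty <- rownames(both_rel)[rowSums(both_rel) > 0]
  d <- bray_curtis(both_rel[nonempty, , drop = FALSE])
  grp <- meta$compartment[match(rownames(d), meta$sample_id)]
  res$distance <- d
  res$anosim <- anosim(d, grp, n_perm = n_perm, seed = seed)
  res$cluster <- cluster_order(d)
  done <- c(done, "community")

  gl_water <- dca_gradient_length(water_rel)
  gut_ok <- gut_rel[!rownames(gut_rel) %in% attr(gut_rel, "empty_samples"),
                    , drop = FALSE]
  gl_gut <- if (nrow(gut_ok) >= 3L) dca_gradient_length(gut_ok) else NULL
  res$gradient <- list(water = gl_water, gut = gl_gut)
  env <- env_matrix(meta, rownames(water_rel))
  res$forward_selection <- forward_select(
    water_rel, env, method = tolower(gl_water$chosen_method),
    alpha = 0.05, n_perm = n_perm, seed = seed)
  # final ordination on the selected drivers; all variables if too few pass
  env_fit <- if (length(res$forward_selection$selected) >= 1L)
    env[, res$forward_selection$selected, drop = FALSE] else env
  res$ordination <- if (gl_water$chosen_method == "CCA")
    cca(water_rel, env_fit) else rda(water_rel, env_fit)
  done <- c(done, "ordination")

  res$report <- list(
    seed = seed, rank = rank, consumer = consumer,
    consumer_rank = consumer_rank,
    thresholds = list(electivity = e_threshold, fdr = fdr_alpha,
                      forward_selection_alpha = 0.05),
    n_permutations = n_perm,
    anosim = list(R = res$anosim$R, p = res$anosim$p,
                  band = res$anosim$band),
    gradient_length_water = gl_water$length,
    gradient_length_gut = if (is.null(gl_gut)) NA_real_ else gl_gut$length,
    ordination_method = res$ordination$method,
    ordination_reason = sprintf(
      "method=%s because water DCA axis-1 gradient length = %.2f SD",
      res$ordination$method, gl_water$length),
    cum_explained_2axes = res$ordination$cum_explained_2axes,
    selected_env = res$forward_selection$selected,
    stages_completed = done,
    r_version = as.character(getRversion()))

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# wide "one row per taxon" selectivity table: Y plus E per season
selectivity_wide <- function(electivity, dominance) {
  taxa <- dominance$taxon
  wide <- data.frame(taxon = taxa,
                     Y = dominance$Y[match(taxa, dominance$taxon)],
                     stringsAsFactors = FALSE)
  for (s in SEASONS) {
    sub <- electivity[electivity$season == s, ]
    wide[[paste0("E_", s)]] <- sub$E[match(taxa, sub$taxon)]
    wide[[paste0("class_", s)]] <- sub$classification[match(taxa, sub$taxon)]
  }
  wide[order(-wide$Y), ]
}

# align two relative-abundance matrices on the union of taxa
merge_compositions <- function(a, b) {
  taxa <- union(colnames(a), colnames(b))
  out <- matrix(0, nrow(a) + nrow(b), length(taxa),
                dimnames = list(c(rownames(a), rownames(b)), taxa))
  out[rownames(a), colnames(a)] <- a
  out[rownames(b), colnames(b)] <- b
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(res$selectivity_table, "selectivity_table.tsv")
  w(res$electivity, "electivity_long.tsv")
  w(res$dominance, "dominance.tsv")
  w(res$enrichment, "enrichment.tsv")
  w(res$rarefaction, "rarefaction.tsv")
  utils::write.table(res$distance, file.path(out_dir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  w(data.frame(set = c(rep("shared", res$venn$n_shared),
                       rep("unique_gut", res$venn$n_unique_a),
                       rep("unique_water", res$venn$n_unique_b)),
               otu_id = c(res$venn$shared, res$venn$unique_a,
                          res$venn$unique_b)), "venn.tsv")
  w(res$forward_selection$trace, "forward_selection.tsv")
  w(data.frame(axis = seq_along(res$ordination$eigenvalues),
               eigenvalue = res$ordination$eigenvalues,
               explained_total = res$ordination$axis_explained,
               explained_constrained =
                 res$ordination$axis_explained_constrained),
    "ordination_eigenvalues.tsv")
  rep_lines <- vapply(names(res$report), function(k)
    paste0(k, ": ", paste(format(unlist(res$report[[k]])), collapse = ", ")),
    character(1L))
  writeLines(rep_lines, file.path(out_dir, "report.txt"))
  writeLines(res$report$stages_completed, file.path(out_dir, "MANIFEST"))
  invisible(out_dir)
}
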