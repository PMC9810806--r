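#!/usr/bin/env Rscript
# Environmentally constrained ordination of the water community: DCA axis-1
# gradient length picks RDA (linear) vs CCA (unimodal), then Monte-Carlo
# permutation forward selection identifies the environmental drivers.

library(rotidiet)

water <- read_otu_table("results/data/water_otu.tsv")
gut <- read_otu_table("results/gut_otu_clean.tsv")
tax <- read_taxonomy("results/data/taxonomy.tsv")
meta <- read_sample_frame("results/data/metadata.tsv")

water_rel <- relative_abundance(aggregate_by_rank(water, tax, "class"))
gut_rel <- relative_abundance(aggregate_by_rank(gut, tax, "class"))

gl_w <- dca_gradient_length(water_rel)
gl_g <- dca_gradient_length(gut_rel)
cat(sprintf("DCA axis-1 gradient length: water %.1f SD -> %s; gut %.1f SD -> %s\n",
            gl_w$length, gl_w$chosen_method,
            gl_g$length, gl_g$chosen_method))

env <- env_matrix(meta, rownames(water_rel))
fs <- forward_select(water_rel, env, method = tolower(gl_w$chosen_method),
                     alpha = 0.05, n_perm = 999, seed = 20)
write.table(fs$trace, "results/forward_selection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Forward selection (999 permutations):",
    if (length(fs$selected)) paste(fs$selected, collapse = ", ")
    else "no variable significant", "\n")
cat("  stopping:", fs$stopping, "\n")

# final ordination on the selected drivers (all variables if none passed)
env_fit <- if (length(fs$selected) >= 1L)
  env[, fs$selected, drop = FALSE] else env
ord <- if (gl_w$chosen_method == "CCA") {
  cca(water_rel, env_fit)
} else {
  rda(water_rel, env_fit)
}
cat(sprintf("%s of water community on %d environmental variables (%s):\n",
            ord$method, ncol(env_fit),
            paste(colnames(env_fit), collapse = ", ")))
cat(sprintf("  constrained/total inertia = %.2f/%.2f (%.0f%%)\n",
            ord$constrained_inertia, ord$total_inertia,
            100 * ord$constrained_inertia / ord$total_inertia))
cat(sprintf("  first two axes explain %.0f%% of the community-environment variability\n",
            100 * ord$cum_explained_2axes))

write.table(data.frame(axis = seq_along(ord$eigenvalues),
                       eigenvalue = ord$eigenvalues,
                       explained_constrained =
                         ord$axis_explained_constrained),
            "results/ordination_eigenvalues.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
n_ax <- min(2L, ncol(ord$site_scores))
write.table(data.frame(sample_id = rownames(ord$site_scores),
                       round(ord$site_scores[, seq_len(n_ax),
                                             drop = FALSE], 4)),
            "results/ordination_site_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
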