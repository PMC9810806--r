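#!/usr/bin/env Rscript
# Consumer self-read removal, rarefaction curves and shared/unique OTU
# accounting on the simulated study from 01_simulate.R.

library(rotidiet)

gut <- read_otu_table("results/data/gut_otu.tsv")
water <- read_otu_table("results/data/water_otu.tsv")
tax <- read_taxonomy("results/data/taxonomy.tsv")

gut_clean <- remove_consumer_reads(gut, tax, "Polyarthra", "genus")
removed <- attr(gut_clean, "removed_reads")
cat(sprintf("Removed %s consumer reads from %d gut libraries (%.1f%% of gut reads)\n",
            format(sum(removed), big.mark = ","), nrow(gut),
            100 * sum(removed) / sum(gut)))
if (length(attr(gut_clean, "empty_samples")))
  cat("  libraries left empty:",
      paste(attr(gut_clean, "empty_samples"), collapse = ", "), "\n")

dir.create("results", showWarnings = FALSE)
write_otu_table(gut_clean, "results/gut_otu_clean.tsv")

rar <- rbind(cbind(compartment = "gut", rarefaction_curves(gut_clean)),
             cbind(compartment = "water", rarefaction_curves(water)))
write.table(rar, "results/rarefaction.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
full <- rar[ave(rar$depth, rar$sample_id, FUN = max) == rar$depth, ]
cat(sprintf("Rarefaction: observed richness %0.f-%0.f OTUs (gut), %0.f-%0.f (water)\n",
            min(full$expected_richness[full$compartment == "gut"]),
            max(full$expected_richness[full$compartment == "gut"]),
            min(full$expected_richness[full$compartment == "water"]),
            max(full$expected_richness[full$compartment == "water"])))

venn <- shared_unique(gut_clean, water)
cat(sprintf("OTUs: %d shared, %d gut-only, %d water-only\n",
            venn$n_shared, venn$n_unique_a, venn$n_unique_b))
write.table(data.frame(set = c(rep("shared", venn$n_shared),
                               rep("unique_gut", venn$n_unique_a),
                               rep("unique_water", venn$n_unique_b)),
                       otu_id = c(venn$shared, venn$unique_a,
                                  venn$unique_b)),
            "results/venn.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
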