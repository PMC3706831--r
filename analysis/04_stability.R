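#!/usr/bin/env Rscript
# Stability of the methylation signature across passages: per-line Spearman
# correlations between passages (and replicate pairs at passage 5),
# delta-beta histograms, and complete-linkage clustering of samples on the
# signature loci.

suppressPackageStartupMessages(library(flsmethylome))
dir.create("results/stability", showWarnings = FALSE, recursive = TRUE)

sheet <- read_sample_sheet("results/cohort/sample_sheet.csv")
sig <- read_signature("results/cohort/signature.txt")
mats <- list()
for (p in c("3", "5", "7"))
  mats[[p]] <- read_beta_matrix(sprintf("results/cohort/beta_P%s.tsv", p),
                                sprintf("results/cohort/detection_P%s.tsv", p))

rep <- passage_stability(mats, sheet, sig)
print(rep)
write.table(rep$averages, "results/stability/averages.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rep$per_line, "results/stability/per_line.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# delta-beta histogram, P5 vs P3, first RA line
s3 <- subset_to_signature(mats[["3"]], sig)
s5 <- subset_to_signature(mats[["5"]], sig)
h <- delta_histogram(s5$beta[, "RA01_P5"], s3$beta[, "RA01_P3"])
write_histogram(h, "results/stability/delta_P5_P3_RA01.tsv")
message(sprintf("delta histogram area: %.12f (should be 1)",
                sum(h$density * 0.01)))

# clustering on the signature at each passage
for (p in names(mats)) {
  ch <- cluster_heatmap(subset_to_signature(mats[[p]], sig))
  write_tree_newick(ch$sample_hclust,
                    sprintf("results/stability/samples_P%s.nwk", p))
  cl <- stats::cutree(ch$sample_hclust, 3)
  pheno <- sheet$phenotype[match(names(cl), sheet$sample_id)]
  purity <- sum(apply(table(cl, pheno), 1, max)) / length(cl)
  message(sprintf("passage %s: 3-cluster phenotype purity %.3f", p, purity))
}
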