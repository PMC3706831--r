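#!/usr/bin/env Rscript
# Differential methylation at passage 5: detection QC, Welch tests with
# Storey q-values for the three primitive phenotype comparisons, promoter
# DMG labelling, and the two derived union sets. Writes per-comparison DML
# and DMG tables under results/dml/ and prints the counts that summarise
# each comparison.

suppressPackageStartupMessages(library(flsmethylome))
dir.create("results/dml", showWarnings = FALSE, recursive = TRUE)

sheet <- read_sample_sheet("results/cohort/sample_sheet.csv")
annot <- read_cpg_annotation("results/cohort/cpg_annotation.tsv")
models <- read_gene_models("results/cohort/gene_models.tsv")
x <- read_beta_matrix("results/cohort/beta_P5.tsv",
                      "results/cohort/detection_P5.tsv")

qcd <- qc_filter_loci(x, threshold = 0.001)
message(sprintf("detection QC: %d of %d loci removed",
                attr(qcd, "n_removed"), nrow(x$beta)))

plans <- build_plans(sheet, passage = 5)
multimap <- map_loci_to_genes(annot, models)

sets <- list()
for (nm in names(plans)) {
  plan <- plans[[nm]]
  if (!is.null(plan$derivation)) next
  tab <- call_dml(qcd, plan$group_a, plan$group_b)
  cts <- attr(tab, "counts")
  message(sprintf("%s: %d tested, %d skipped, %d DML (%d hyper / %d hypo)",
                  nm, cts["tested"], cts["skipped"], cts["dml"],
                  cts["hyper"], cts["hypo"]))
  write_dml_table(tab, sprintf("results/dml/dml_%s.tsv", gsub("\\+", "p", nm)))
  sets[[nm]] <- call_dmgs(tab, multimap, nm)
}
for (nm in names(plans)) {
  plan <- plans[[nm]]
  if (is.null(plan$derivation)) next
  sets[[nm]] <- combine_dmg_sets(sets, plan$derivation, nm)
}
for (nm in names(sets)) {
  message(sprintf("DMGs in %s: %d", nm, length(sets[[nm]]$genes)))
  write_dmg_set(sets[[nm]], sprintf("results/dml/dmg_%s.tsv",
                                    gsub("\\+", "p", nm)))
}
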