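#!/usr/bin/env Rscript
# Over-representation of the combined DMG set in the synthetic pathway
# database: hypergeometric p-values, Storey q-values and enrichment factors
# on the chip-restricted background. Confirms that the planted pathways are
# recovered at the top of the ranking.

suppressPackageStartupMessages(library(flsmethylome))
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

annot <- read_cpg_annotation("results/cohort/cpg_annotation.tsv")
models <- read_gene_models("results/cohort/gene_models.tsv")
db <- read_gmt("results/cohort/pathways.gmt", source = "KEGG")
multimap <- map_loci_to_genes(annot, models)
chip_genes <- unique(multimap$gene_symbol)

# re-read the combined DMG set written by 02_dml_dmg.R
dmg_tab <- read.delim("results/dml/dmg_combined.tsv", comment.char = "#")
res <- enrich(dmg_tab$gene_symbol, db, chip_genes)
write_enrichment(res, "results/enrichment/enrichment_KEGG.tsv")

message(sprintf("%d of %d covered pathways significant at q < 0.05",
                sum(res$significant), nrow(res)))
top <- utils::head(res[, c("pathway_id", "k", "K", "percentage", "EF",
                           "q_value")], 5)
message(paste(utils::capture.output(print(top, row.names = FALSE)),
              collapse = "\n"))

truth <- read.delim("results/cohort/truth_pathways.tsv")
planted <- truth$pathway_id[truth$is_planted_enriched]
message(sprintf("planted pathways %s rank %s by q",
                paste(planted, collapse = ", "),
                paste(match(planted, res$pathway_id), collapse = ", ")))
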