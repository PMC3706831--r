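#!/usr/bin/env Rscript
# Generate the default synthetic cohort: 11 RA / 11 OA / 6 NL cell lines at
# passages 3, 5 and 7 on a 20,000-locus array, with planted RA- and
# NL-specific promoter methylation differences, a pathway database in which
# two pathways concentrate planted DMG genes, and technical replicates at
# passage 5 for the stability analysis.

suppressPackageStartupMessages(library(flsmethylome))

cfg <- sim_config(p5_replicates = TRUE, seed = 20260920)
sim <- simulate_cohort(cfg, "results/cohort")

truth <- sim$truth
message(sprintf("wrote cohort to results/cohort: %d loci x %d samples",
                cfg$n_loci, nrow(sim$sheet)))
message(sprintf("planted RA-effect loci: %d (in %d genes); NL-effect loci: %d",
                sum(truth$loci$is_planted_dml),
                sum(truth$genes$is_planted_dmg),
                sum(truth$loci$is_planted_nl)))
message(sprintf("signature size: %d loci; planted enriched pathways: %s",
                length(sim$signature),
                paste(truth$pathways$pathway_id[
                  truth$pathways$is_planted_enriched], collapse = ", ")))
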