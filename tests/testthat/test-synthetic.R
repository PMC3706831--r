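test_that("config validation rejects impossible settings", {
  expect_error(sim_config(miss_rate = 1.2), "rates")
  expect_error(sim_config(effect_size = -0.1), "effect")
  expect_error(sim_config(group_sizes = c(RA = 0, OA = 3, NL = 3)),
               "cell line")
  expect_error(sim_config(n_loci = 20, frac_dml = 0.01), "config error")
})

test_that("the same seed reproduces byte-identical output files", {
  cfg <- sim_config(n_loci = 400, n_genes = 60,
                    group_sizes = c(RA = 3, OA = 3, NL = 2),
                    passages = c(3, 5), seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(cfg, d1)
  s2 <- simulate_cohort(cfg, d2)
  for (nm in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]),
                     info = nm)
  }
})

test_that("emitted files round-trip through the package readers", {
  cfg <- sim_config(n_loci = 300, n_genes = 50,
                    group_sizes = c(RA = 3, OA = 3, NL = 2),
                    passages = c(5), seed = 7)
  d <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, d)
  x <- read_beta_matrix(sim$paths$beta_P5, sim$paths$detection_P5)
  expect_identical(x$beta, sim$matrices[["5"]]$beta)
  expect_identical(x$detection_p, sim$matrices[["5"]]$detection_p)
  expect_equal(read_sample_sheet(sim$paths$sheet)$sample_id,
               sim$sheet$sample_id)
  models <- read_gene_models(sim$paths$models)
  expect_equal(models$tss, sim$models$tss)
  db <- read_gmt(sim$paths$gmt)
  expect_equal(lapply(db$entries, `[[`, "genes"),
               lapply(sim$db$entries, `[[`, "genes"))
  expect_equal(read_signature(sim$paths$signature), sim$signature)
})

test_that("truth tables are consistent with the annotation and promoter rule", {
  sim <- small_cohort(701)
  truth <- sim$truth$loci
  mm <- map_loci_to_genes(sim$annotation, sim$models)
  rederived <- sort(unique(
    mm$gene_symbol[mm$locus_id %in% truth$locus_id[truth$is_planted_dml]]))
  expect_identical(
    rederived,
    sort(sim$truth$genes$gene_symbol[sim$truth$genes$is_planted_dmg]))
  # every planted DML lies in a promoter
  expect_true(all(truth$in_promoter[truth$is_planted_dml]))
  # RA and NL planted sets are disjoint
  expect_length(which(truth$is_planted_dml & truth$is_planted_nl), 0)
  # planted deltas honour the configured magnitude
  expect_true(all(abs(truth$planted_delta[truth$is_planted_dml]) ==
                    sim$config$effect_size))
})

test_that("pooled beta values are bimodal at the default baseline mixture", {
  sim <- small_cohort(702)
  pooled <- as.numeric(sim$matrices[["5"]]$beta)
  pooled <- pooled[!is.na(pooled)]
  h <- hist(pooled, breaks = seq(0, 1, 0.05), plot = FALSE)
  dens <- h$density
  # two well-separated peaks with a valley below half the smaller peak
  lo_peak <- max(dens[1:6]); hi_peak <- max(dens[15:20])
  valley <- min(dens[7:14])
  expect_gt(lo_peak, 2 * valley)
  expect_gt(hi_peak, 2 * valley)
})

test_that("missingness and detection-failure rates match configuration within 3 SE", {
  cfg <- sim_config(n_loci = 5000, n_genes = 300,
                    group_sizes = c(RA = 4, OA = 4, NL = 3),
                    passages = c(5), miss_rate = 0.02,
                    det_fail_rate = 0.01, seed = 703)
  sim <- simulate_cohort(cfg, write = FALSE)
  m <- sim$matrices[["5"]]
  ncell <- length(m$beta)
  miss <- mean(is.na(m$beta))
  se_miss <- sqrt(0.02 * 0.98 / ncell)
  expect_lt(abs(miss - 0.02), 3 * se_miss)
  fail <- mean(m$detection_p > 0.01, na.rm = TRUE)
  se_fail <- sqrt(0.01 * 0.99 / sum(!is.na(m$detection_p)))
  expect_lt(abs(fail - 0.01), 3 * se_fail)
})

test_that("null configuration yields DML counts at the false-positive level", {
  cfg <- sim_config(n_loci = 4000, n_genes = 300, frac_dml = 0, nl_frac = 0,
                    group_sizes = c(RA = 6, OA = 6, NL = 3),
                    passages = c(5), seed = 704)
  sim <- simulate_cohort(cfg, write = FALSE)
  sheet <- sim$sheet
  tab <- call_dml(sim$matrices[["5"]],
                  sheet$sample_id[sheet$phenotype == "RA"],
                  sheet$sample_id[sheet$phenotype == "OA"])
  expect_lte(sum(tab$is_dml), 0.01 * nrow(tab))
})

test_that("passage_correlation_of reflects the configured noise ladder", {
  cfg <- sim_config(p7_extra_sd = 0.05)
  ord <- passage_correlation_of(cfg)
  expect_equal(ord$expected_rank[ord$pair == "P3-P5"], 1)
  expect_gt(ord$combined_sd[ord$pair == "P3-P7"],
            ord$combined_sd[ord$pair == "P3-P5"])

  flat <- passage_correlation_of(sim_config(p7_extra_sd = 0))
  expect_true(all(flat$expected_rank == 1))
  expect_equal(length(unique(flat$combined_sd)), 1)

  expect_error(passage_correlation_of(sim_config(passages = 5)), ">= 2")
})

test_that("vanishing assay noise drives inter-passage correlations to one", {
  sim <- small_cohort(705, assay_sd = 1e-4, p7_extra_sd = 0,
                      miss_rate = 0, det_fail_rate = 0)
  rep <- passage_stability(sim$matrices, sim$sheet, sim$signature)
  expect_true(all(rep$averages$mean_rho > 0.999))
})
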