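test_that("signature subsetting preserves signature order and reports absences", {
  x <- bm(matrix(runif(20), 5, 4))
  sig <- c("cg004", "cg001", "cg999")
  s <- subset_to_signature(x, sig)
  expect_equal(rownames(s$beta), c("cg004", "cg001"))
  expect_equal(attr(s, "absent"), "cg999")
  full <- subset_to_signature(x, c("cg002", "cg003"))
  expect_equal(nrow(full$beta), 2)
  expect_error(subset_to_signature(x, "cg999"), "no signature locus")
})

test_that("pairwise Spearman omits incomplete pairs and handles edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_pairwise(x, x), 1)
  expect_equal(spearman_pairwise(x, rev(x)), -1)
  expect_equal(spearman_pairwise(c(1, 2, 3, 4, NA), c(2, 1, 4, 3, 5)), 0.6)
  expect_true(is.na(spearman_pairwise(c(1, 2, NA, NA, NA),
                                      c(1, 2, 3, 4, 5))))
  # invariance under strictly monotone transforms
  set.seed(601)
  a <- runif(50); b <- runif(50); a[c(3, 9)] <- NA
  expect_equal(spearman_pairwise(a, b), spearman_pairwise(exp(a), b^3))
  expect_equal(spearman_pairwise(a, b), spearman_pairwise(log(a + 1), b))
})

test_that("passage stability averages per-line correlations and sees replicates", {
  sim <- small_cohort(602, p5_replicates = TRUE)
  rep <- passage_stability(sim$matrices, sim$sheet, sim$signature)
  expect_setequal(rep$averages$pair, c("P3-P5", "P3-P7", "P5-P7"))
  expect_equal(unique(rep$averages$n_lines), 9)
  expect_true(all(rep$per_line$rho >= -1 & rep$per_line$rho <= 1))
  expect_equal(nrow(rep$replicates), 9)
  # replicates of the same passage correlate at least as well on average as
  # cross-passage pairs involving the extra-noise passage
  expect_gt(mean(rep$replicates$rho),
            rep$averages$mean_rho[rep$averages$pair == "P5-P7"])

  # a duplicated sample as a fake replicate gives rho exactly 1
  m5 <- sim$matrices[["5"]]
  s <- sample_ids(m5)[1]
  expect_equal(spearman_pairwise(m5$beta[, s], m5$beta[, s]), 1)
})

test_that("single shared line and two passages reduce to one correlation", {
  sim <- small_cohort(603)
  sheet <- sim$sheet[sim$sheet$cell_line_id == "RA01", ]
  mats <- sim$matrices[c("3", "5")]
  rep <- passage_stability(mats, sheet, sim$signature)
  expect_equal(nrow(rep$per_line), 1)
  expect_equal(rep$averages$mean_rho, rep$per_line$rho)
})

test_that("delta histograms use fixed 0.01 bins and integrate to one", {
  a <- matrix(runif(300), 100, 3)
  h <- delta_histogram(a, a)
  expect_equal(sum(h$density * 0.01), 1, tolerance = 1e-12)
  expect_equal(h$density[which.min(abs(h$bin_start))], 100)  # all mass at zero
  expect_equal(sum(h$density > 0), 1)

  h2 <- delta_histogram(rep(0.155, 10), rep(0.1, 10))
  expect_equal(h2$density[which.min(abs(h2$bin_start - 0.05))], 100)

  set.seed(604)
  h3 <- delta_histogram(runif(5000), runif(5000))
  expect_equal(sum(h3$density * 0.01), 1, tolerance = 1e-12)
  expect_true(all(h3$density >= 0))
  expect_error(delta_histogram(NA_real_, 0.5), "no complete pairs")
})

test_that("complete-linkage clustering follows hand agglomeration", {
  # three samples with engineered Euclidean distances d12=1, d13=5, d23~4
  m <- matrix(c(0, 0, 1, 0, 4.899, 1), nrow = 2)  # cols are samples
  dimnames(m) <- list(c("l1", "l2"), c("s1", "s2", "s3"))
  d <- as.matrix(dist(t(m)))
  expect_equal(d["s1", "s2"], 1, tolerance = 1e-3)
  expect_equal(d["s1", "s3"], 5, tolerance = 1e-3)
  hc <- hclust(dist(t(m)), method = "complete")
  expect_equal(hc$height, c(1, 5), tolerance = 1e-3)  # {1,2} first, then at 5
  expect_setequal(hc$merge[1, ], c(-1, -2))   # first merge joins s1 and s2

  # identical samples merge at height zero
  x <- bm(matrix(c(0.2, 0.8, 0.2, 0.8, 0.5, 0.1), 2, 3))
  ch <- cluster_heatmap(x)
  expect_equal(min(ch$sample_hclust$height), 0)
  expect_equal(dim(ch$ordered_matrix), dim(x$beta))
  expect_true(all(sort(ch$sample_hclust$order) == 1:3))
})

test_that("clustering errors name a sample pair sharing no observed loci", {
  b <- matrix(c(0.1, NA, 0.2, NA, NA, 0.3, NA, 0.4), 4, 2,
              dimnames = list(sprintf("cg%d", 1:4), c("sA", "sB")))
  expect_error(cluster_heatmap(BetaMatrix(b)),
               "'s[AB]' and 's[AB]' share no observed locus")
})

test_that("sample clustering is invariant to input order up to relabeling", {
  sim <- small_cohort(605)
  m5 <- subset_to_signature(sim$matrices[["5"]], sim$signature)
  ch1 <- cluster_heatmap(m5)
  set.seed(1)
  perm <- sample(colnames(m5$beta))
  ch2 <- cluster_heatmap(subset_beta(m5, samples = perm))
  c1 <- cutree(ch1$sample_hclust, 3)
  c2 <- cutree(ch2$sample_hclust, 3)[names(c1)]
  expect_equal(adjusted_rand(c1, c2), 1)
})

test_that("newick export writes a tree containing every sample once", {
  sim <- small_cohort(606)
  ch <- cluster_heatmap(subset_to_signature(sim$matrices[["5"]],
                                            sim$signature))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(ch$sample_hclust, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, sample_ids(sim$matrices[["5"]]))
})
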