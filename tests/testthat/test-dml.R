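test_that("detection QC removes exactly the loci with any failing value", {
  d <- matrix(1e-4, 3, 4)
  x <- bm(matrix(runif(12), 3, 4), detection = d)
  expect_identical(qc_filter_loci(x)$beta, x$beta)
  expect_equal(attr(qc_filter_loci(x), "n_removed"), 0L)

  d[2, 3] <- 0.002
  x2 <- bm(x$beta, detection = d)
  f <- qc_filter_loci(x2)
  expect_equal(nrow(f$beta), 2)
  expect_equal(attr(f, "n_removed"), 1L)
  expect_false("cg002" %in% rownames(f$beta))

  d[] <- 0.5
  expect_warning(all_gone <- qc_filter_loci(bm(x$beta, detection = d)),
                 "all loci")
  expect_equal(nrow(all_gone$beta), 0)

  # no detection matrix: filter is a no-op
  expect_equal(attr(qc_filter_loci(bm(x$beta)), "n_removed"), 0L)
})

test_that("group_values drops missing and detection-masked values", {
  b <- matrix(c(0.1, 0.2, NA, 0.4, 0.5), 1, 5)
  d <- matrix(c(1e-4, 1e-4, 1e-4, 0.02, 1e-4), 1, 5)
  x <- bm(b, detection = d)
  v <- group_values(x, "cg001", sample_ids(x))
  expect_length(v, 3)
  expect_setequal(unname(v), c(0.1, 0.2, 0.5))

  expect_length(group_values(x, "cg001", character(0)), 0)
  expect_error(group_values(x, "cg001", "nope"), "unknown sample")

  # all clean values pass
  clean <- bm(matrix(runif(5), 1, 5),
              detection = matrix(1e-4, 1, 5))
  expect_length(group_values(clean, "cg001", sample_ids(clean)), 5)
})

test_that("welch_test matches the hand formula and handles degeneracy", {
  r <- welch_test(c(0.8, 0.7, 0.9), c(0.2, 0.1, 0.3))
  expect_equal(r$t_stat, 7.348, tolerance = 1e-3)
  expect_equal(r$df, 4, tolerance = 1e-6)
  expect_equal(r$p_value, 0.0018, tolerance = 2e-2)

  same <- welch_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  swapped <- welch_test(c(0.2, 0.1, 0.3), c(0.8, 0.7, 0.9))
  expect_equal(swapped$t_stat, -r$t_stat)
  expect_equal(swapped$p_value, r$p_value)

  const_eq <- welch_test(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(const_eq$p_value, 1)
  const_ne <- welch_test(c(0.5, 0.5), c(0.7, 0.7))
  expect_equal(const_ne$p_value, 0)
  expect_equal(const_ne$t_stat, -Inf)
})

test_that("welch_test agrees with independent implementations on random pairs", {
  set.seed(202)
  for (i in 1:1000) {
    x <- runif(sample(2:12, 1)); y <- runif(sample(2:12, 1))
    got <- welch_test(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$t_stat, want$t_stat, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
  # spot-check a handful against stats::t.test as a second route
  set.seed(203)
  for (i in 1:25) {
    x <- rnorm(6); y <- rnorm(9, 0.3)
    tt <- t.test(x, y)
    got <- welch_test(x, y)
    expect_equal(got$t_stat, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("storey q-values follow the step-up with pi0 and stay monotone in p", {
  # pi0 pinned at 1: plain step-up q(i) = min_{j>=i} p(j) m / j
  q <- storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(as.numeric(q), rep(0.04, 4))

  expect_equal(as.numeric(storey_qvalues(rep(1, 5), pi0 = 1)), rep(1, 5))
  expect_length(storey_qvalues(numeric(0)), 0)

  set.seed(204)
  p <- runif(500)
  q <- storey_qvalues(p)
  expect_true(all(q <= 1 & q >= 0))
  expect_false(is.unsorted(q[order(p)]))
})

test_that("storey q-values match a from-definition reference on simulated vectors", {
  set.seed(205)
  for (i in 1:100) {
    m <- sample(c(30, 120, 250), 1)
    p <- c(runif(m), rbeta(sample(5:20, 1), 1, 30))
    expect_equal(as.numeric(storey_qvalues(p)), oracle_qvalues(p),
                 tolerance = 1e-6)
  }
})

test_that("pi0 estimate is near 1 for uniform p-values", {
  set.seed(206)
  q <- storey_qvalues(runif(10000))
  expect_gte(attr(q, "pi0"), 0.85)
  expect_lte(attr(q, "pi0"), 1.0)
})

test_that("call_dml applies the min-per-group, q and delta rules", {
  set.seed(207)
  nloc <- 200; nA <- 5; nB <- 5
  b <- matrix(runif(nloc * (nA + nB), 0.4, 0.6), nloc)
  # locus 1: strong planted difference
  b[1, 1:nA] <- 0.85 + runif(nA, -0.02, 0.02)
  b[1, (nA + 1):(nA + nB)] <- 0.15 + runif(nB, -0.02, 0.02)
  # locus 2: only 2 usable values in group A
  b[2, 1:3] <- NA
  x <- bm(b)
  A <- sprintf("s%02d", 1:nA); B <- sprintf("s%02d", (nA + 1):(nA + nB))
  tab <- call_dml(x, A, B)
  expect_equal(tab$skipped_reason[2], "too_few_values")
  expect_true(is.na(tab$p_value[2]) && is.na(tab$q_value[2]))
  expect_true(tab$is_dml[1])
  expect_equal(tab$direction[1], "hyper")
  expect_gt(tab$delta[1], 0.1)
  # DML requires BOTH thresholds: big delta with big q must not pass
  big_delta <- abs(tab$delta) > 0.1 & tab$q_value >= 0.05
  expect_true(all(!tab$is_dml[which(big_delta)]))
  # a locus is hyper iff DML with positive delta
  expect_identical(tab$direction == "hyper", tab$is_dml & tab$delta > 0)
})

test_that("DML calls are invariant to locus and sample ordering", {
  sim <- small_cohort(208)
  x <- sim$matrices[["5"]]
  sheet <- sim$sheet
  A <- sheet$sample_id[sheet$phenotype == "RA" & sheet$passage == 5]
  B <- sheet$sample_id[sheet$phenotype == "OA" & sheet$passage == 5]
  tab1 <- call_dml(x, A, B)
  set.seed(1)
  perm <- subset_beta(x, loci = sample(rownames(x$beta)),
                      samples = sample(colnames(x$beta)))
  tab2 <- call_dml(perm, sample(A), rev(B))
  tab2 <- tab2[match(tab1$locus_id, tab2$locus_id), ]
  expect_equal(tab1$is_dml, tab2$is_dml)
  expect_equal(tab1$q_value, tab2$q_value)
})

test_that("lowering min_per_group never reduces the tested set", {
  sim <- small_cohort(209, miss_rate = 0.2)
  x <- sim$matrices[["5"]]
  sheet <- sim$sheet
  A <- sheet$sample_id[sheet$phenotype == "RA" & sheet$passage == 5]
  B <- sheet$sample_id[sheet$phenotype == "OA" & sheet$passage == 5]
  n3 <- sum(call_dml(x, A, B, min_per_group = 3)$skipped_reason == "none")
  n2 <- sum(call_dml(x, A, B, min_per_group = 2)$skipped_reason == "none")
  expect_gte(n2, n3)
})
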