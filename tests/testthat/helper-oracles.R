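# Independent oracles used across the suite. Each re-derives a quantity by
# a route different from the implementation under test.

# quick BetaMatrix fixture
bm <- function(values, nloc = NULL, nsam = NULL, detection = NULL) {
  if (is.matrix(values)) m <- values
  else m <- matrix(values, nloc, nsam)
  if (is.null(rownames(m))) rownames(m) <- sprintf("cg%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (!is.null(detection) && is.null(dimnames(detection)))
    dimnames(detection) <- dimnames(m)
  BetaMatrix(m, detection)
}

# Welch's t-test by the textbook formula, scalar arithmetic only
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# q-values straight from the definition: q(p_i) is the smallest estimated
# pFDR over rejection thresholds t >= p_i, with thresholds at observed ps.
oracle_qvalues <- function(p, pi0 = NULL) {
  m <- length(p)
  if (is.null(pi0)) pi0 <- oracle_pi0(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) pi0 * m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

oracle_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) < 100) return(1)
  pi0_l <- sapply(lambda, function(l) mean(p > l) / (1 - l))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  min(max(stats::predict(fit, x = max(lambda))$y, .Machine$double.eps), 1)
}

# exact upper-tail hypergeometric by direct enumeration over choose()
oracle_hyper <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# brute-force locus -> gene promoter mapping by all-pairs position scan
oracle_map <- function(annot, models, up = 2500, down = 500) {
  out <- list()
  for (i in seq_len(nrow(annot))) {
    for (j in seq_len(nrow(models))) {
      if (annot$chromosome[i] != models$chromosome[j]) next
      tss <- models$tss[j]
      if (models$strand[j] == "+") { lo <- tss - up; hi <- tss + down }
      else { lo <- tss - down; hi <- tss + up }
      lo <- max(lo, 1)
      if (annot$position[i] >= lo && annot$position[i] <= hi)
        out[[length(out) + 1]] <- data.frame(
          locus_id = annot$locus_id[i],
          gene_symbol = models$gene_symbol[j],
          transcript_id = models$transcript_id[j],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(locus_id = character(0), gene_symbol = character(0),
                      transcript_id = character(0)))
  do.call(rbind, out)
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small stability-sized cohort used by several suites; ... overrides defaults
small_cohort <- function(seed, ...) {
  args <- list(n_loci = 2000, n_genes = 200,
               group_sizes = c(RA = 3, OA = 3, NL = 3), seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_cohort(do.call(sim_config, args), write = FALSE)
}
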