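#' Dataset-level detection-p QC filter
#'
#' Removes every locus at which any sample has a detection p-value above the
#' threshold. This is the chip-level QC step applied once per dataset,
#' before any group comparison; the per-value masking used during testing
#' (threshold 0.01) is a separate, later stage (see [group_values()]).
#'
#' @param x a [BetaMatrix].
#' @param threshold detection p-value above which a value fails QC
#'   (default 0.001).
#' @return A `BetaMatrix` restricted to passing loci, with attribute
#'   `n_removed` giving the number of filtered loci. A matrix without
#'   detection p-values is returned unchanged.
#' @export
qc_filter_loci <- function(x, threshold = 0.001) {
  if (is.null(x$detection_p)) {
    attr(x, "n_removed") <- 0L
    return(x)
  }
  fails <- x$detection_p > threshold
  fails[is.na(fails)] <- FALSE      # missing values carry no detection call
  bad <- rowSums(fails) > 0
  if (all(bad)) warning("all loci failed detection QC; empty matrix returned")
  out <- subset_beta(x, loci = rownames(x$beta)[!bad])
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Usable beta values of one locus in one sample group
#'
#' Returns the beta values of `locus` among `samples` that are non-missing
#' and whose detection p-value does not exceed `mask_threshold`. This is the
#' per-value masking applied during differential testing.
#'
#' @param x a [BetaMatrix].
#' @param locus a single locus id.
#' @param samples character vector of sample ids.
#' @param mask_threshold detection p-value above which a single value is
#'   excluded (default 0.01).
#' @return Named numeric vector of usable values (may be empty).
#' @export
group_values <- function(x, locus, samples, mask_threshold = 0.01) {
  if (length(samples) == 0) return(numeric(0))
  unknown <- setdiff(samples, colnames(x$beta))
  if (length(unknown)) stop("unknown sample id(s): ",
                            paste(unknown, collapse = ", "))
  if (!locus %in% rownames(x$beta)) stop("unknown locus id: ", locus)
  b <- x$beta[locus, samples]
  d <- detection_or_zero(x)[locus, samples]
  keep <- !is.na(b) & !is.na(d) & d <= mask_threshold
  b[keep]
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs follow explicit conventions:
#' when both groups have zero variance and equal means, `t = 0, p = 1`;
#' when both have zero variance but unequal means the difference is
#' noiseless, so `t = Inf` (signed) and `p = 0`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return List with `t_stat`, `df`, `p_value`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_test requires at least 2 values per group")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / length(x) + vy / length(y)
  if (se2 == 0) {
    if (mx == my) return(list(t_stat = 0, df = NA_real_, p_value = 1))
    return(list(t_stat = sign(mx - my) * Inf, df = NA_real_, p_value = 0))
  }
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                 (vy / length(y))^2 / (length(y) - 1))
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Storey q-values
#'
#' Converts p-values to q-values controlling the positive false discovery
#' rate. The null proportion pi0 is estimated by the smoother method on the
#' lambda grid 0.05, 0.10, ..., 0.95 (natural cubic smoothing spline with
#' 3 df, evaluated at the largest lambda) and clamped to (0, 1]. For fewer
#' than 100 p-values the smoother is unstable and pi0 is fixed at 1, which
#' reduces to the Benjamini-Hochberg step-up and is conservative.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed; propagated).
#' @param pi0 optionally override the estimated null proportion.
#' @return Numeric vector of q-values, same length and order as `p`, with
#'   attribute `pi0`.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0) return(p)
  if (any(pv < 0 | pv > 1)) stop("p-values outside [0, 1]")
  if (is.null(pi0)) pi0 <- estimate_pi0(pv)
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pv[o] / seq(m, 1)))[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}

estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 100) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Call differentially methylated loci between two sample groups
#'
#' For every locus, usable values are collected per group (non-missing and
#' detection p <= `mask_threshold`); a locus is skipped when either group
#' retains fewer than `min_per_group` values. Welch's t-test is applied to
#' the remaining loci, p-values are converted to q-values jointly across all
#' tested loci of this comparison, and a locus is flagged as a DML when
#' `q < q_thresh` and `|delta| > delta_thresh` (strict inequalities), where
#' `delta = mean(group A) - mean(group B)`. Direction `hyper` means higher
#' methylation in group A.
#'
#' @param x a [BetaMatrix].
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @param q_thresh,delta_thresh DML thresholds (defaults 0.05 and 0.1).
#' @param min_per_group minimum usable values per group (default 3).
#' @param mask_threshold per-value detection p mask (default 0.01).
#' @return data.frame (one row per locus, input order) with columns
#'   `locus_id, mean_a, mean_b, delta, n_a, n_b, t_stat, df, p_value,
#'   q_value, is_dml, direction, skipped_reason`.
#' @export
call_dml <- function(x, group_a, group_b, q_thresh = 0.05,
                     delta_thresh = 0.1, min_per_group = 3,
                     mask_threshold = 0.01) {
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  unknown <- setdiff(c(group_a, group_b), colnames(x$beta))
  if (length(unknown)) stop("unknown sample id(s): ",
                            paste(unknown, collapse = ", "))

  d <- detection_or_zero(x)
  usable <- !is.na(x$beta) & !is.na(d) & d <= mask_threshold
  b <- x$beta
  b[!usable] <- NA

  stats_for <- function(samples) {
    bs <- b[, samples, drop = FALSE]
    n <- rowSums(!is.na(bs))
    s <- rowSums(bs, na.rm = TRUE)
    mean <- ifelse(n > 0, s / n, NA_real_)
    ss <- rowSums(bs^2, na.rm = TRUE)
    var <- ifelse(n > 1, (ss - n * mean^2) / (n - 1), NA_real_)
    var <- pmax(var, 0)   # guard tiny negative rounding residue
    list(n = n, mean = mean, var = var)
  }
  a <- stats_for(group_a)
  bb <- stats_for(group_b)

  tested <- a$n >= min_per_group & bb$n >= min_per_group
  delta <- a$mean - bb$mean
  se2 <- a$var / a$n + bb$var / bb$n
  t_stat <- df <- p <- rep(NA_real_, nrow(b))

  pos <- tested & se2 > 0
  t_stat[pos] <- delta[pos] / sqrt(se2[pos])
  df[pos] <- se2[pos]^2 /
    ((a$var[pos] / a$n[pos])^2 / (a$n[pos] - 1) +
     (bb$var[pos] / bb$n[pos])^2 / (bb$n[pos] - 1))
  p[pos] <- 2 * stats::pt(-abs(t_stat[pos]), df[pos])
  deg <- tested & se2 == 0            # both groups constant
  t_stat[deg] <- ifelse(delta[deg] == 0, 0, sign(delta[deg]) * Inf)
  p[deg] <- ifelse(delta[deg] == 0, 1, 0)

  q <- rep(NA_real_, nrow(b))
  if (any(tested)) q[tested] <- storey_qvalues(p[tested])
  if (!any(tested)) warning("no testable loci in this comparison")

  is_dml <- !is.na(q) & q < q_thresh & abs(delta) > delta_thresh
  direction <- ifelse(is_dml, ifelse(delta > 0, "hyper", "hypo"), "none")

  res <- data.frame(
    locus_id = rownames(b),
    mean_a = ifelse(tested, a$mean, NA_real_),
    mean_b = ifelse(tested, bb$mean, NA_real_),
    delta = ifelse(tested, delta, NA_real_),
    n_a = a$n, n_b = bb$n,
    t_stat = t_stat, df = df, p_value = p, q_value = q,
    is_dml = is_dml, direction = direction,
    skipped_reason = ifelse(tested, "none", "too_few_values"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "counts") <- c(tested = sum(tested), skipped = sum(!tested),
                           dml = sum(is_dml),
                           hyper = sum(direction == "hyper"),
                           hypo = sum(direction == "hypo"))
  res
}

#' Write a locus test table to TSV
#' @param tab data.frame from [call_dml()].
#' @param path output path.
#' @export
write_dml_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
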