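#' Construct a BetaMatrix
#'
#' The central container of the pipeline: a loci x samples matrix of
#' methylation fractions (beta values) with an optional parallel matrix of
#' per-value detection p-values. Missing measurements are `NA` in both
#' matrices.
#'
#' @param beta numeric matrix of beta values in \[0, 1\] (or `NA`), with
#'   unique rownames (CpG locus ids) and unique colnames (sample ids).
#' @param detection_p optional numeric matrix of detection p-values in
#'   \[0, 1\], same dimensions and dimnames as `beta`. `NULL` means
#'   detection p-values are unavailable and every value is treated as
#'   reliably detected (p = 0).
#' @return An object of class `BetaMatrix`.
#' @examples
#' b <- matrix(c(0.1, 0.9, NA, 0.5), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' BetaMatrix(b)
#' @export
BetaMatrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("'beta' must be a numeric matrix")
  if ((nrow(beta) > 0 && is.null(rownames(beta))) ||
      (ncol(beta) > 0 && is.null(colnames(beta))))
    stop("'beta' must have locus rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate locus ids in beta matrix")
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids in beta matrix")
  if (length(beta) && !all(is.na(beta))) {
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop("beta values outside [0, 1]")
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(beta)))
      stop("'detection_p' must be a matrix with the same shape as 'beta'")
    if (!identical(dimnames(detection_p), dimnames(beta)))
      stop("'detection_p' dimnames must match 'beta'")
    if (length(detection_p) && !all(is.na(detection_p))) {
      dp <- range(detection_p, na.rm = TRUE)
      if (dp[1] < 0 || dp[2] > 1) stop("detection p-values outside [0, 1]")
    }
  }
  structure(list(beta = beta, detection_p = detection_p),
            class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d loci x %d samples (%d missing values, detection p %s)\n",
              nrow(x$beta), ncol(x$beta), sum(is.na(x$beta)),
              if (is.null(x$detection_p)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$beta)

#' Locus and sample identifiers of a BetaMatrix
#' @param x a `BetaMatrix`.
#' @return Character vector of ids.
#' @export
locus_ids <- function(x) rownames(x$beta)

#' @rdname locus_ids
#' @export
sample_ids <- function(x) colnames(x$beta)

#' Subset a BetaMatrix by loci and/or samples
#'
#' @param x a `BetaMatrix`.
#' @param loci,samples character vectors of ids (or indices); `NULL` keeps all.
#' @return A `BetaMatrix` restricted to the requested rows/columns, in the
#'   requested order.
#' @export
subset_beta <- function(x, loci = NULL, samples = NULL) {
  if (is.null(loci)) loci <- rownames(x$beta)
  if (is.null(samples)) samples <- colnames(x$beta)
  b <- x$beta[loci, samples, drop = FALSE]
  d <- if (is.null(x$detection_p)) NULL else
    x$detection_p[loci, samples, drop = FALSE]
  BetaMatrix(b, d)
}

# Detection p-value matrix with absent detection treated as all zero.
detection_or_zero <- function(x) {
  if (is.null(x$detection_p)) {
    d <- matrix(0, nrow(x$beta), ncol(x$beta), dimnames = dimnames(x$beta))
    d[is.na(x$beta)] <- NA
    d
  } else x$detection_p
}
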