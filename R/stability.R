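#' Restrict a BetaMatrix to a CpG signature
#'
#' Rows are restricted to the signature ids, preserving the signature's
#' order; ids absent from the matrix are reported in the `absent` attribute.
#'
#' @param x a [BetaMatrix].
#' @param sig character vector of signature locus ids.
#' @return A `BetaMatrix` with attribute `absent`.
#' @export
subset_to_signature <- function(x, sig) {
  present <- sig[sig %in% rownames(x$beta)]
  if (length(present) == 0)
    stop("no signature locus present in the matrix")
  out <- subset_beta(x, loci = present)
  attr(out, "absent") <- setdiff(sig, present)
  out
}

#' Spearman correlation on pairwise-complete observations
#'
#' Rank correlation computed on the pairs where both vectors are observed,
#' with average ranks for ties. Fewer than 3 complete pairs is reported as
#' `NA` rather than a coefficient.
#'
#' @param x,y numeric vectors of equal length, `NA` allowed.
#' @return Spearman rho, or `NA` when under 3 complete pairs remain.
#' @export
spearman_pairwise <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Inter-passage stability of a CpG signature
#'
#' For every cell line present in at least two passages, computes the
#' Spearman correlation of signature beta values between each passage pair,
#' plus replicate-pair correlations within the same line (samples sharing a
#' `replicate_label` group), then averages each passage pair across lines.
#'
#' @param matrices named list `passage -> BetaMatrix` (names are passage
#'   numbers as character).
#' @param sheet sample sheet data.frame.
#' @param sig signature locus ids.
#' @return A `StabilityReport`: list with `per_line` (data.frame cell_line,
#'   pair, rho), `averages` (data.frame pair, mean_rho, n_lines), and
#'   `replicates` (data.frame cell_line, rho; zero rows when the sheet has
#'   no replicates).
#' @export
passage_stability <- function(matrices, sheet, sig) {
  passages <- sort(as.integer(names(matrices)))
  if (length(passages) < 2) stop("need at least two passages")
  sub <- lapply(matrices, subset_to_signature, sig = sig)

  sample_of <- function(line, pass) {
    s <- sheet$sample_id[sheet$cell_line_id == line &
                           sheet$passage == pass &
                           is.na(sheet$replicate_label)]
    if (length(s) == 0) NA_character_ else s[1]
  }
  lines <- unique(sheet$cell_line_id)
  pairs <- utils::combn(passages, 2, simplify = FALSE)

  per_line <- do.call(rbind, lapply(lines, function(ln) {
    do.call(rbind, lapply(pairs, function(pr) {
      s1 <- sample_of(ln, pr[1]); s2 <- sample_of(ln, pr[2])
      m1 <- sub[[as.character(pr[1])]]; m2 <- sub[[as.character(pr[2])]]
      if (is.na(s1) || is.na(s2) ||
          !s1 %in% colnames(m1$beta) || !s2 %in% colnames(m2$beta))
        return(NULL)
      common <- intersect(rownames(m1$beta), rownames(m2$beta))
      rho <- spearman_pairwise(m1$beta[common, s1], m2$beta[common, s2])
      data.frame(cell_line = ln, pair = paste0("P", pr[1], "-P", pr[2]),
                 rho = rho, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(per_line) || nrow(per_line) == 0)
    stop("no cell line is shared between two passages")

  averages <- do.call(rbind, lapply(split(per_line, per_line$pair),
    function(d) data.frame(pair = d$pair[1],
                           mean_rho = mean(d$rho, na.rm = TRUE),
                           n_lines = sum(!is.na(d$rho)),
                           stringsAsFactors = FALSE)))
  rownames(averages) <- NULL

  # replicate pairs: same line, same passage, one flagged with a label
  replicates <- do.call(rbind, lapply(lines, function(ln) {
    reps <- sheet[sheet$cell_line_id == ln & !is.na(sheet$replicate_label), ]
    if (nrow(reps) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
      pass <- as.character(reps$passage[i])
      if (!pass %in% names(sub)) return(NULL)
      m <- sub[[pass]]
      s0 <- sample_of(ln, reps$passage[i])
      s1 <- reps$sample_id[i]
      if (is.na(s0) || !all(c(s0, s1) %in% colnames(m$beta))) return(NULL)
      data.frame(cell_line = ln,
                 rho = spearman_pairwise(m$beta[, s0], m$beta[, s1]),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(replicates))
    replicates <- data.frame(cell_line = character(0), rho = numeric(0))

  structure(list(per_line = per_line, averages = averages,
                 replicates = replicates), class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat("StabilityReport\n  average Spearman rho per passage pair:\n")
  for (i in seq_len(nrow(x$averages)))
    cat(sprintf("    %s: %.4f (%d lines)\n", x$averages$pair[i],
                x$averages$mean_rho[i], x$averages$n_lines[i]))
  if (nrow(x$replicates))
    cat(sprintf("  replicate rho (mean over %d pairs): %.4f\n",
                nrow(x$replicates), mean(x$replicates$rho, na.rm = TRUE)))
  invisible(x)
}

#' Histogram of between-passage beta differences
#'
#' Differences `a - b` over matched loci/samples (complete pairs only) are
#' binned at fixed 0.01-wide bins whose edges sit at multiples of the bin
#' width over \[-1, 1\] (left-closed, right-open; the last bin closed), and
#' reported as densities: `count / (total * binwidth)`, so the bar areas
#' sum to one.
#'
#' @param a,b numeric matrices or vectors of matched beta values.
#' @param binwidth bin width (default 0.01).
#' @return data.frame `bin_start`, `bin_end`, `density`.
#' @export
delta_histogram <- function(a, b, binwidth = 0.01) {
  d <- as.numeric(a) - as.numeric(b)
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no complete pairs to difference")
  edges <- seq.int(-round(1 / binwidth), round(1 / binwidth)) * binwidth
  h <- graphics::hist(d, breaks = edges, right = FALSE, plot = FALSE)
  data.frame(bin_start = utils::head(edges, -1), bin_end = edges[-1],
             density = h$counts / (length(d) * binwidth))
}

#' Hierarchical clustering of samples and loci for heat-map export
#'
#' Beta values are scaled to percentages (x100); Euclidean distances are
#' computed on pairwise-complete dimensions and rescaled proportionally to
#' the full dimensionality; both axes are clustered by complete-linkage
#' agglomeration. Missing values are preserved in the exported (ordered)
#' matrix so a renderer can paint them white.
#'
#' @param x a [BetaMatrix] with >= 2 samples.
#' @return List with `sample_hclust`, `locus_hclust` (`hclust` objects) and
#'   `ordered_matrix` (percentage matrix in dendrogram order, `NA` kept).
#' @export
cluster_heatmap <- function(x) {
  pct <- x$beta * 100
  if (ncol(pct) < 2) stop("need at least 2 samples to cluster")
  ds <- stats::dist(t(pct))                 # pairwise-complete, rescaled
  if (anyNA(ds)) {
    dm <- as.matrix(ds)
    bad <- which(is.na(dm), arr.ind = TRUE)[1, ]
    stop(sprintf("samples '%s' and '%s' share no observed locus",
                 rownames(dm)[bad[1]], colnames(dm)[bad[2]]))
  }
  sample_hc <- stats::hclust(ds, method = "complete")
  dl <- stats::dist(pct)
  if (anyNA(dl)) {
    dm <- as.matrix(dl)
    bad <- which(is.na(dm), arr.ind = TRUE)[1, ]
    stop(sprintf("loci '%s' and '%s' share no observed sample",
                 rownames(dm)[bad[1]], colnames(dm)[bad[2]]))
  }
  locus_hc <- stats::hclust(dl, method = "complete")
  list(sample_hclust = sample_hc, locus_hclust = locus_hc,
       ordered_matrix = pct[locus_hc$order, sample_hc$order, drop = FALSE])
}

#' Export a clustering tree as Newick
#' @param hc an `hclust` object.
#' @param path output path.
#' @export
write_tree_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a delta-beta histogram to TSV
#' @param h data.frame from [delta_histogram()].
#' @param path output path.
#' @export
write_histogram <- function(h, path) {
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
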