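#' Chip-restricted background for over-representation analysis
#'
#' The background N is the union of all database gene sets intersected with
#' the genes covered by the array (i.e. genes whose promoters contain
#' measured CpGs); each pathway's covered set is likewise intersected.
#' Pathways left with no covered genes are excluded from testing.
#'
#' @param db a `PathwayDB` from [read_gmt()].
#' @param genes_on_chip character vector of covered gene symbols.
#' @return List with `background` (character vector N) and `covered`
#'   (named list pathway id -> covered gene vector, empty sets dropped).
#' @export
covered_background <- function(db, genes_on_chip) {
  if (length(db$entries) == 0 || length(genes_on_chip) == 0)
    stop("empty pathway database or chip gene set")
  all_genes <- unique(unlist(lapply(db$entries, `[[`, "genes")))
  background <- intersect(all_genes, genes_on_chip)
  if (length(background) == 0)
    stop("no database gene is covered by the chip: empty background")
  covered <- lapply(db$entries, function(e) intersect(e$genes, background))
  covered <- covered[vapply(covered, length, integer(1)) > 0]
  list(background = background, covered = covered)
}

#' Enrichment factor
#'
#' `EF = (k/K) / (n/N)`: the fraction of a pathway's covered genes that are
#' DMGs, relative to the DMG fraction of the covered background.
#'
#' @param k DMGs in the pathway.
#' @param K covered genes in the pathway.
#' @param n DMGs in the background.
#' @param N background size.
#' @return The fold enrichment (`NA` for an untestable pathway with
#'   `K = 0` or `n = 0`).
#' @export
enrichment_factor <- function(k, K, n, N) {
  ifelse(K > 0 & n > 0, (k / K) / (n / N), NA_real_)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for X the number of pathway genes among `n` genes drawn
#' without replacement from a background of `N` genes containing `K`
#' pathway genes (inclusive upper tail).
#'
#' @param k observed overlap.
#' @param K pathway size (covered).
#' @param n number of draws (DMGs in background).
#' @param N background size.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(k < 0 | K > N | n > N | k > K | k > n))
    stop("inconsistent hypergeometric parameters")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a DMG set
#'
#' For each pathway with covered genes, counts the overlap k with the DMG
#' set, computes the enrichment factor, the percentage 100*k/K (half-even
#' rounded to one decimal), the inclusive upper-tail hypergeometric p-value,
#' and Storey q-values across all tested pathways of this database.
#' Significance is `q < 0.05`. By default the DMG count n is restricted to
#' DMGs inside the covered background.
#'
#' @param dmg a `DMGSet` (or character vector of gene symbols).
#' @param db a `PathwayDB`.
#' @param chip_genes genes covered by the array.
#' @param q_thresh significance threshold on q (default 0.05).
#' @param restrict_n if `TRUE` (default) n counts DMGs within the covered
#'   background; if `FALSE`, all DMGs.
#' @return data.frame sorted by (q, EF descending) with columns
#'   `pathway_id, pathway_name, k, K, n, N, EF, percentage, p_value,
#'   q_value, significant`.
#' @export
enrich <- function(dmg, db, chip_genes, q_thresh = 0.05, restrict_n = TRUE) {
  genes <- if (inherits(dmg, "DMGSet")) names(dmg$genes) else dmg
  bg <- covered_background(db, chip_genes)
  N <- length(bg$background)
  dmg_in_bg <- intersect(genes, bg$background)
  n <- if (restrict_n) length(dmg_in_bg) else length(genes)

  ids <- names(bg$covered)
  K <- vapply(bg$covered, length, integer(1))
  k <- vapply(bg$covered, function(g) length(intersect(g, dmg_in_bg)),
              integer(1))
  p <- if (n == 0) rep(1, length(ids)) else
    vapply(seq_along(ids), function(i)
      hypergeom_pvalue(k[i], K[i], min(n, N), N), numeric(1))
  q <- as.numeric(storey_qvalues(p))
  res <- data.frame(
    pathway_id = ids,
    pathway_name = vapply(db$entries[ids], `[[`, character(1), "name"),
    k = k, K = K, n = n, N = N,
    EF = enrichment_factor(k, K, n, N),
    percentage = round(100 * k / K, 1),
    p_value = p, q_value = q,
    significant = q < q_thresh,
    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$q_value, -res$EF), ]
}

#' Write an enrichment table to TSV
#' @param res data.frame from [enrich()].
#' @param path output path.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
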