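#' Promoter window of a transcript
#'
#' The promoter is the 3 kb interval around the transcription start site,
#' from 2500 bp upstream to 500 bp downstream, with offsets applied in the
#' direction of transcription: on the + strand `[tss - up, tss + down]`, on
#' the - strand `[tss - down, tss + up]` (1-based inclusive ends; 3001
#' positions at the defaults). Windows running off the chromosome start are
#' clipped to position 1 with a warning.
#'
#' @param model one-row data.frame (or list) with fields `transcript_id`,
#'   `chromosome`, `strand`, `tss`.
#' @param up,down upstream/downstream extents in bp (defaults 2500 and 500).
#' @return List with `transcript_id`, `chromosome`, `start`, `end`, `strand`.
#' @export
promoter_window <- function(model, up = 2500, down = 500) {
  if (model$strand == "+") {
    start <- model$tss - up; end <- model$tss + down
  } else if (model$strand == "-") {
    start <- model$tss - down; end <- model$tss + up
  } else stop("unknown strand: ", model$strand)
  if (start < 1) {
    warning("promoter window clipped at chromosome start for ",
            model$transcript_id)
    start <- 1
  }
  list(transcript_id = model$transcript_id, chromosome = model$chromosome,
       start = as.integer(start), end = as.integer(end),
       strand = model$strand)
}

promoter_windows <- function(models, up = 2500, down = 500) {
  plus <- models$strand == "+"
  start <- ifelse(plus, models$tss - up, models$tss - down)
  end <- ifelse(plus, models$tss + down, models$tss + up)
  start <- pmax(start, 1)
  data.frame(gene_symbol = models$gene_symbol,
             transcript_id = models$transcript_id,
             chromosome = models$chromosome,
             start = as.integer(start), end = as.integer(end),
             strand = models$strand, stringsAsFactors = FALSE)
}

#' Map CpG loci to genes via promoter windows
#'
#' A locus maps to a gene iff its position falls inside the promoter window
#' (inclusive ends) of any transcript of that gene. A locus may map to
#' several genes when promoters overlap.
#'
#' @param annot CpG annotation data.frame (`locus_id`, `chromosome`,
#'   `position`).
#' @param models gene-model data.frame from [read_gene_models()].
#' @param up,down promoter extents passed to the window rule.
#' @return data.frame multimap with columns `locus_id`, `gene_symbol`,
#'   `transcript_id` (one row per locus-transcript hit, deduplicated at the
#'   locus-gene level in [call_dmgs()]).
#' @export
map_loci_to_genes <- function(annot, models, up = 2500, down = 500) {
  win <- promoter_windows(models, up = up, down = down)
  hits <- lapply(unique(win$chromosome), function(chr) {
    wi <- win[win$chromosome == chr, , drop = FALSE]
    ai <- annot[annot$chromosome == chr, , drop = FALSE]
    if (nrow(wi) == 0 || nrow(ai) == 0) return(NULL)
    q <- IRanges::IRanges(start = ai$position, width = 1)
    s <- IRanges::IRanges(start = wi$start, end = wi$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) return(NULL)
    data.frame(locus_id = ai$locus_id[S4Vectors::queryHits(ov)],
               gene_symbol = wi$gene_symbol[S4Vectors::subjectHits(ov)],
               transcript_id = wi$transcript_id[S4Vectors::subjectHits(ov)],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(locus_id = character(0), gene_symbol = character(0),
                       transcript_id = character(0), stringsAsFactors = FALSE)
  hits
}

#' Label differentially methylated genes from a locus test table
#'
#' A gene is a DMG iff at least one DML lies in any of its promoter windows.
#' Per-gene status summarises the supporting DML directions: `hyper` when
#' all supporting loci are hypermethylated in group A, `hypo` when all are
#' hypomethylated, `mixed` when both occur.
#'
#' @param dml_table data.frame from [call_dml()].
#' @param multimap locus-to-gene map from [map_loci_to_genes()].
#' @param comparison_name label stored with the set.
#' @return A `DMGSet`: list with `comparison_name`, `genes` (named character
#'   vector gene -> status) and `supporting` (named list gene ->
#'   data.frame(locus_id, direction)).
#' @export
call_dmgs <- function(dml_table, multimap, comparison_name = "comparison") {
  dml <- dml_table[dml_table$is_dml, c("locus_id", "direction")]
  hits <- merge(dml, unique(multimap[, c("locus_id", "gene_symbol")]),
                by = "locus_id")
  genes <- character(0); supporting <- list()
  if (nrow(hits)) {
    hits <- hits[order(hits$gene_symbol, hits$locus_id), ]
    supporting <- split(hits[, c("locus_id", "direction")], hits$gene_symbol)
    genes <- vapply(supporting, function(s) {
      dirs <- unique(s$direction)
      if (length(dirs) > 1) "mixed" else dirs
    }, character(1))
  }
  structure(list(comparison_name = comparison_name, genes = genes,
                 supporting = supporting), class = "DMGSet")
}

#' @export
print.DMGSet <- function(x, ...) {
  cat(sprintf("DMGSet '%s': %d genes (%d hyper, %d hypo, %d mixed)\n",
              x$comparison_name, length(x$genes),
              sum(x$genes == "hyper"), sum(x$genes == "hypo"),
              sum(x$genes == "mixed")))
  invisible(x)
}

#' Write a DMG set to TSV
#' @param dmg a `DMGSet`.
#' @param path output path.
#' @export
write_dmg_set <- function(dmg, path) {
  g <- names(dmg$genes)
  df <- data.frame(
    gene_symbol = g,
    status = unname(dmg$genes),
    n_supporting = vapply(dmg$supporting[g], nrow, integer(1)),
    supporting_loci = vapply(dmg$supporting[g], function(s)
      paste(s$locus_id, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# comparison: %s", dmg$comparison_name), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
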