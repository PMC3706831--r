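#' Read a beta-value matrix (and optional detection p-values) from TSV
#'
#' The expected dialect is a tab-separated table whose first column holds the
#' CpG locus id and whose header row names the samples. Empty cells, `NA` and
#' `NaN` denote missing measurements. A detection p-value table of identical
#' shape may live in a parallel TSV; if absent, every value is treated as
#' reliably detected.
#'
#' @param path path to the beta TSV.
#' @param detection_path optional path to a detection p-value TSV of the same
#'   shape (same loci, same samples, same order).
#' @return A [BetaMatrix].
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path, detection_path = NULL) {
  beta <- read_value_matrix(path, what = "beta")
  if (!all(is.na(beta)) &&
      (min(beta, na.rm = TRUE) < 0 || max(beta, na.rm = TRUE) > 1))
    stop("beta values outside [0, 1] in ", path)
  det <- NULL
  if (!is.null(detection_path)) {
    det <- read_value_matrix(detection_path, what = "detection p")
    if (!identical(dim(det), dim(beta)))
      stop("detection matrix shape differs from beta matrix")
    if (!identical(dimnames(det), dimnames(beta)))
      stop("detection matrix loci/samples differ from beta matrix")
  }
  BetaMatrix(beta, det)
}

read_value_matrix <- function(path, what = "value") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          na.strings = c("", "NA", "NaN"),
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("malformed ", what, " matrix: need id column + samples")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate locus ids in ", path)
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids in header of ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, samples)
  m
}

#' Write a BetaMatrix to TSV
#'
#' Values are written with full double precision so that a
#' write/read round trip is exact; missing values are written as `NA`.
#'
#' @param x a [BetaMatrix].
#' @param path output path for the beta TSV.
#' @param detection_path optional output path for the detection p TSV
#'   (ignored when `x` carries no detection matrix).
#' @export
write_beta_matrix <- function(x, path, detection_path = NULL) {
  write_value_matrix(x$beta, path)
  if (!is.null(detection_path) && !is.null(x$detection_p))
    write_value_matrix(x$detection_p, detection_path)
  invisible(path)
}

write_value_matrix <- function(m, path) {
  chr <- matrix(sprintf("%.17g", m), nrow(m))
  chr[is.na(m)] <- "NA"
  out <- cbind(locus_id = rownames(m), chr)
  colnames(out) <- c("locus_id", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample sheet
#'
#' Comma- or tab-separated table with columns `sample_id`, `phenotype`
#' (RA/OA/NL), `cell_line_id`, `passage` and optionally `replicate_label`.
#'
#' @param path path to the CSV/TSV sample sheet.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype", "cell_line_id", "passage")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sheet")
  bad <- setdiff(unique(df$phenotype), c("RA", "OA", "NL"))
  if (length(bad)) stop("unknown phenotype: ", paste(bad, collapse = ", "))
  if (!"replicate_label" %in% colnames(df)) df$replicate_label <- NA_character_
  df$passage <- as.integer(df$passage)
  df
}

#' @rdname read_sample_sheet
#' @param sheet data.frame as returned by `read_sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CpG genomic annotation table
#'
#' TSV with columns `locus_id`, `chromosome`, `position` (1-based).
#'
#' @param path path to the annotation TSV.
#' @return data.frame with unique locus ids.
#' @export
read_cpg_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("locus_id", "chromosome", "position")
  if (!all(need %in% colnames(df)))
    stop("annotation lacks columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  if (anyDuplicated(df$locus_id)) stop("duplicate locus ids in annotation")
  df$position <- as.integer(df$position)
  if (any(df$position < 1)) stop("positions must be >= 1")
  df
}

#' @rdname read_cpg_annotation
#' @param annot data.frame of CpG annotation.
#' @export
write_cpg_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene/transcript models with transcription start sites
#'
#' Accepts either a refFlat-style TSV (`gene_symbol`, `transcript_id`,
#' `chromosome`, `strand`, `txStart`, `txEnd`; coordinates 0-based half-open
#' in the UCSC convention) or BED6 (no header; `name` is the transcript id
#' and the gene symbol). All coordinates are converted to 1-based at the
#' boundary: the TSS is `txStart + 1` on the + strand and `txEnd` on the
#' - strand.
#'
#' @param path path to the refFlat TSV or BED6 file.
#' @param format `"refflat"`, `"bed6"`, or `"auto"` (sniff: BED has no header
#'   and 6 columns with numeric 2nd/3rd fields).
#' @return data.frame with columns `gene_symbol`, `transcript_id`,
#'   `chromosome`, `strand`, `tss` (1-based).
#' @export
read_gene_models <- function(path, format = c("auto", "refflat", "bed6")) {
  format <- match.arg(format)
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (format == "auto") {
    looks_bed <- length(first) >= 6 && !is.na(suppressWarnings(
      as.numeric(first[2]))) && !is.na(suppressWarnings(as.numeric(first[3])))
    format <- if (looks_bed) "bed6" else "refflat"
  }
  if (format == "bed6") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED6 requires 6 columns")
    models <- data.frame(gene_symbol = df[[4]], transcript_id = df[[4]],
                         chromosome = df[[1]], strand = df[[6]],
                         txStart = as.integer(df[[2]]),
                         txEnd = as.integer(df[[3]]),
                         stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene_symbol", "transcript_id", "chromosome", "strand",
              "txStart", "txEnd")
    if (!all(need %in% colnames(df)))
      stop("refFlat table lacks columns: ",
           paste(setdiff(need, colnames(df)), collapse = ", "))
    models <- df[, need]
  }
  if (!all(models$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(setdiff(unique(models$strand), c("+", "-")), collapse = ", "))
  if (anyDuplicated(models$transcript_id))
    stop("duplicate transcript ids")
  models$tss <- ifelse(models$strand == "+",
                       models$txStart + 1L, as.integer(models$txEnd))
  models[, c("gene_symbol", "transcript_id", "chromosome", "strand", "tss")]
}

#' @rdname read_gene_models
#' @param models data.frame of gene models including `txStart`/`txEnd`
#'   0-based half-open (as produced by the simulator).
#' @export
write_gene_models <- function(models, path) {
  utils::write.table(models, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One gene set per line: set id, description, then member gene symbols,
#' tab-separated. Duplicate genes within a line are removed.
#'
#' @param path path to the GMT file.
#' @param source database label, e.g. `"KEGG"` or `"GO"`.
#' @return A `PathwayDB`: list with `source` and `entries`, the latter a
#'   named list of `list(name =, genes =)` keyed by pathway id.
#' @export
read_gmt <- function(path, source = "KEGG") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  entries <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields")
    id <- f[1]
    if (id %in% names(entries)) stop("duplicate pathway id in GMT: ", id)
    entries[[id]] <- list(name = f[2], genes = unique(f[-(1:2)]))
  }
  structure(list(source = source, entries = entries), class = "PathwayDB")
}

#' @rdname read_gmt
#' @param db a `PathwayDB`.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$entries), function(id) {
    e <- db$entries[[id]]
    paste(c(id, e$name, e$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a CpG signature list (one locus id per line)
#'
#' @param path path to the plain-text list.
#' @return Character vector of unique locus ids, in file order.
#' @export
read_signature <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) stop("duplicate ids in signature list")
  ids
}

#' @rdname read_signature
#' @param ids character vector of locus ids.
#' @export
write_signature <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
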