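#' Assemble a pipeline configuration
#'
#' Collects input paths and the analysis thresholds. Defaults are the
#' study's parameters: dataset QC at detection p 0.001, per-value masking
#' at 0.01, DML thresholds q < 0.05 and |delta| > 0.1, minimum 3 values per
#' group, promoter window -2500..+500 around the TSS.
#'
#' @param paths named list of input paths: `beta` (named by passage),
#'   `detection` (optional, named by passage), `sheet`, `annotation`,
#'   `models`, `gmt` (may be a named vector of databases), `signature`.
#' @param passage passage whose samples enter the group comparisons
#'   (default 5).
#' @param qc_detect,mask_detect,q_thresh,delta_thresh,min_per_group,window_up,window_down
#'   analysis thresholds (see Details).
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(paths, passage = 5, qc_detect = 0.001,
                            mask_detect = 0.01, q_thresh = 0.05,
                            delta_thresh = 0.1, min_per_group = 3,
                            window_up = 2500, window_down = 500,
                            seed = 1, out_dir = "pipeline_out") {
  stopifnot(qc_detect >= 0, qc_detect <= 1, mask_detect >= 0,
            mask_detect <= 1, q_thresh >= 0, q_thresh <= 1,
            delta_thresh >= 0, min_per_group >= 2,
            window_up >= 0, window_down >= 0)
  structure(list(paths = paths, passage = passage, qc_detect = qc_detect,
                 mask_detect = mask_detect, q_thresh = q_thresh,
                 delta_thresh = delta_thresh, min_per_group = min_per_group,
                 window_up = window_up, window_down = window_down,
                 seed = seed, out_dir = out_dir),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes QC -> DML calling per primitive comparison -> promoter DMG
#' labelling -> comparison-set union -> enrichment per gene-set database ->
#' passage stability, writing every stage's table plus a deterministic run
#' manifest (input/output md5 hashes, seed, per-stage counts) under the
#' configured output directory.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `manifest` and the in-memory stage
#'   results (`dml`, `dmgs`, `enrichment`, `stability`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  p <- config$paths
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  counts <- list()

  sheet <- read_sample_sheet(p$sheet)
  annot <- read_cpg_annotation(p$annotation)
  models <- read_gene_models(p$models)
  sig <- read_signature(p$signature)

  matrices <- list()
  for (pass in names(p$beta)) {
    det <- if (!is.null(p$detection)) p$detection[[pass]] else NULL
    matrices[[pass]] <- read_beta_matrix(p$beta[[pass]], det)
  }

  ## QC, then DML per primitive comparison at the analysis passage
  key <- as.character(config$passage)
  if (!key %in% names(matrices))
    stop("pipeline error [qc]: no beta matrix for passage ", key)
  qcd <- qc_filter_loci(matrices[[key]], config$qc_detect)
  counts$qc_removed <- attr(qcd, "n_removed")

  plans <- build_plans(sheet, config$passage)
  multimap <- map_loci_to_genes(annot, models, up = config$window_up,
                                down = config$window_down)
  chip_genes <- unique(multimap$gene_symbol[
    multimap$locus_id %in% rownames(qcd$beta)])

  dml_tables <- list(); dmg_sets <- list()
  for (nm in names(plans)) {
    plan <- plans[[nm]]
    if (!is.null(plan$derivation)) next
    tab <- call_dml(qcd, plan$group_a, plan$group_b,
                    q_thresh = config$q_thresh,
                    delta_thresh = config$delta_thresh,
                    min_per_group = config$min_per_group,
                    mask_threshold = config$mask_detect)
    dml_tables[[nm]] <- tab
    write_dml_table(tab, file.path(config$out_dir,
                                   sprintf("dml_%s.tsv", gsub("\\+", "p", nm))))
    dmg_sets[[nm]] <- call_dmgs(tab, multimap, comparison_name = nm)
    counts[[paste0("dml_", nm)]] <- unname(attr(tab, "counts")["dml"])
    counts[[paste0("dmg_", nm)]] <- length(dmg_sets[[nm]]$genes)
  }
  for (nm in names(plans)) {
    plan <- plans[[nm]]
    if (is.null(plan$derivation)) next
    dmg_sets[[nm]] <- combine_dmg_sets(dmg_sets, plan$derivation,
                                       comparison_name = nm)
    counts[[paste0("dmg_", nm)]] <- length(dmg_sets[[nm]]$genes)
  }
  for (nm in names(dmg_sets))
    write_dmg_set(dmg_sets[[nm]],
                  file.path(config$out_dir,
                            sprintf("dmg_%s.tsv", gsub("\\+", "p", nm))))

  ## enrichment of the combined set against each database
  gmts <- p$gmt
  if (is.null(names(gmts))) names(gmts) <- paste0("db", seq_along(gmts))
  enrichment <- list()
  for (dbnm in names(gmts)) {
    db <- read_gmt(gmts[[dbnm]], source = dbnm)
    res <- enrich(dmg_sets$combined, db, chip_genes,
                  q_thresh = config$q_thresh)
    enrichment[[dbnm]] <- res
    write_enrichment(res, file.path(config$out_dir,
                                    sprintf("enrichment_%s.tsv", dbnm)))
    counts[[paste0("significant_", dbnm)]] <- sum(res$significant)
  }

  ## signature stability across passages
  stability <- NULL
  if (length(matrices) >= 2) {
    stability <- passage_stability(matrices, sheet, sig)
    utils::write.table(stability$averages,
                       file.path(config$out_dir, "stability_averages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stability$per_line,
                       file.path(config$out_dir, "stability_per_line.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## deterministic manifest: inputs + outputs hashed, seed, counts
  outs <- sort(list.files(config$out_dir, full.names = TRUE))
  outs <- outs[basename(outs) != "manifest.json"]
  ins <- sort(unname(unlist(p)))
  manifest <- list(
    seed = config$seed,
    passage = config$passage,
    thresholds = config[c("qc_detect", "mask_detect", "q_thresh",
                          "delta_thresh", "min_per_group", "window_up",
                          "window_down")],
    counts = counts,
    input_md5 = as.list(tools::md5sum(ins)),
    output_md5 = as.list(tools::md5sum(outs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, dml = dml_tables, dmgs = dmg_sets,
                 enrichment = enrichment, stability = stability))
}
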