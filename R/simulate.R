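#' Configuration for a synthetic methylation cohort
#'
#' Defines the study conditions the generator emulates: a three-phenotype
#' cohort of cultured cell lines (RA/OA/NL) assayed at up to three passages
#' on a beta-value array with bimodal baselines, planted group-level
#' methylation differences, line-to-line and assay noise, missing values and
#' detection failures.
#'
#' @param n_loci number of CpG loci on the synthetic array.
#' @param n_genes number of genes on the synthetic chromosome (10 kb
#'   spacing, alternating strands, so promoter windows never overlap).
#' @param prom_frac fraction of loci placed inside promoter windows.
#' @param frac_dml fraction of promoter loci given a planted RA-vs-others
#'   mean shift.
#' @param effect_size absolute beta shift of planted RA loci (signed mix,
#'   balanced hyper/hypo where the baseline allows).
#' @param nl_frac fraction of promoter loci (disjoint from the RA set)
#'   given a planted NL-vs-others shift, so that normal lines are
#'   distinguishable from diseased lines as in real cohorts.
#' @param nl_effect_size absolute beta shift of planted NL loci.
#' @param line_sd between-cell-line noise SD on the beta scale.
#' @param assay_sd within-line per-sample measurement SD on the beta scale.
#' @param p7_extra_sd additional SD at passage 7 (senescence drift).
#' @param miss_rate fraction of cells masked missing.
#' @param det_fail_rate fraction of values with failed detection
#'   (detection p drawn above 0.01; all others below 0.001).
#' @param group_sizes named integer vector: cell lines per phenotype.
#' @param passages subset of c(3, 5, 7).
#' @param p5_replicates if `TRUE`, every line gets a technical replicate at
#'   passage 5 (fresh assay noise, same line effect).
#' @param n_pathways,genes_per_pathway gene-set database dimensions.
#' @param n_planted_pathways pathways enriched for planted DMG genes.
#' @param planted_gene_frac fraction of a planted pathway's genes drawn from
#'   planted DMG genes (default 0.6).
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_loci = 20000, n_genes = 1000, prom_frac = 0.6,
                       frac_dml = 0.02, effect_size = 0.3,
                       nl_frac = 0.0125, nl_effect_size = 0.2,
                       line_sd = 0.05, assay_sd = 0.05, p7_extra_sd = 0.08,
                       miss_rate = 0.01, det_fail_rate = 0.001,
                       group_sizes = c(RA = 11, OA = 11, NL = 6),
                       passages = c(3, 5, 7), p5_replicates = FALSE,
                       n_pathways = 40, genes_per_pathway = 25,
                       n_planted_pathways = 2, planted_gene_frac = 0.6,
                       seed = 1) {
  cfg <- list(n_loci = n_loci, n_genes = n_genes, prom_frac = prom_frac,
              frac_dml = frac_dml, effect_size = effect_size,
              nl_frac = nl_frac, nl_effect_size = nl_effect_size,
              line_sd = line_sd, assay_sd = assay_sd,
              p7_extra_sd = p7_extra_sd, miss_rate = miss_rate,
              det_fail_rate = det_fail_rate, group_sizes = group_sizes,
              passages = sort(passages), p5_replicates = p5_replicates,
              n_pathways = n_pathways,
              genes_per_pathway = genes_per_pathway,
              n_planted_pathways = n_planted_pathways,
              planted_gene_frac = planted_gene_frac, seed = seed)
  rates <- c(frac_dml, nl_frac, miss_rate, det_fail_rate, prom_frac,
             planted_gene_frac)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (effect_size < 0 || nl_effect_size < 0)
    stop("effect sizes must be >= 0")
  if (any(group_sizes < 1)) stop("each group needs >= 1 cell line")
  if (!all(passages %in% c(3, 5, 7))) stop("passages must be within {3,5,7}")
  if (frac_dml > 0 && frac_dml * n_loci < 1)
    stop("config error: frac_dml * n_loci < 1, no locus to plant")
  structure(cfg, class = "SimConfig")
}

# logit-scale noise SD giving approximately `sd_beta` on the beta scale at
# mean mu (delta method; derivative floored so boundary loci get bounded
# logit noise and hence less beta-scale variance, as on real arrays).
logit_noise_sd <- function(mu, sd_beta) sd_beta / pmax(mu * (1 - mu), 0.1)

#' Generate a complete synthetic cohort on disk
#'
#' Emits one beta + detection TSV per passage, a sample sheet, CpG
#' annotation, refFlat gene models, a GMT database with planted enriched
#' pathways, a signature locus list (the union of planted RA-effect and
#' NL-effect loci) and truth tables, all in the formats the readers in this
#' package consume. Baseline methylation is drawn from a bimodal
#' beta-mixture (modes near 0.1 and 0.85); noise is added on the logit
#' scale and inverse-transformed so values stay in (0, 1).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed; unused when
#'   `write = FALSE`).
#' @param write if `FALSE`, generate in memory only and emit no files
#'   (`paths` is then `NULL`). The realisation is identical either way for
#'   a given seed.
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (loci/genes/pathways truth tables), `matrices` (passage ->
#'   [BetaMatrix]), `sheet`, `annotation`, `models`, `db`, `signature`,
#'   `config`.
#' @export
simulate_cohort <- function(config, dir = NULL, write = !is.null(dir)) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  if (write) {
    if (is.null(dir)) stop("'dir' is required when write = TRUE")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }

  ## gene models on one synthetic chromosome, 10 kb spacing
  ng <- config$n_genes
  gene_symbol <- sprintf("g%04d", seq_len(ng))
  transcript_id <- sprintf("t%04d", seq_len(ng))
  strand <- rep(c("+", "-"), length.out = ng)
  tss <- 10000L * seq_len(ng)
  txStart <- ifelse(strand == "+", tss - 1L, tss - 2001L)
  txEnd <- ifelse(strand == "+", tss + 2000L, tss)
  models <- data.frame(gene_symbol, transcript_id, chromosome = "chrS",
                       strand, txStart = as.integer(txStart),
                       txEnd = as.integer(txEnd), tss = tss,
                       stringsAsFactors = FALSE)

  ## loci: a fraction inside promoters, the rest mid-gap (never in a window)
  nl <- config$n_loci
  n_prom <- round(config$prom_frac * nl)
  locus_id <- sprintf("cg%06d", seq_len(nl))
  prom_gene <- sample.int(ng, n_prom, replace = TRUE)
  offset <- sample(-2500:500, n_prom, replace = TRUE)   # TSS-relative
  prom_pos <- ifelse(strand[prom_gene] == "+",
                     tss[prom_gene] + offset, tss[prom_gene] - offset)
  inter_pos <- 10000L * sample.int(ng, nl - n_prom, replace = TRUE) +
    5000L + sample(-1500:1500, nl - n_prom, replace = TRUE)
  position <- as.integer(pmax(c(prom_pos, inter_pos), 1))
  annotation <- data.frame(locus_id, chromosome = "chrS", position,
                           stringsAsFactors = FALSE)
  in_promoter <- c(rep(TRUE, n_prom), rep(FALSE, nl - n_prom))

  ## bimodal baseline
  low <- stats::runif(nl) < 0.5
  base <- ifelse(low, stats::rbeta(nl, 2, 18), stats::rbeta(nl, 17, 3))
  base <- pmin(pmax(base, 0.01), 0.99)

  ## planted RA effect on promoter loci; NL effect on a disjoint subset
  plant_shift <- function(candidates, n_plant, effect) {
    idx <- sort(sample(candidates, n_plant))
    delta <- numeric(length(idx))
    for (i in seq_along(idx)) {
      b <- base[idx[i]]
      up_ok <- b + effect <= 0.98
      dn_ok <- b - effect >= 0.02
      s <- if (up_ok && dn_ok) sample(c(-1, 1), 1) else if (up_ok) 1 else -1
      delta[i] <- s * effect
    }
    list(idx = idx, delta = delta)
  }
  prom_idx <- which(in_promoter)
  n_ra <- floor(config$frac_dml * n_prom)
  ra <- plant_shift(prom_idx, n_ra, config$effect_size)
  n_nl_loci <- floor(config$nl_frac * n_prom)
  nl_eff <- plant_shift(setdiff(prom_idx, ra$idx), n_nl_loci,
                        config$nl_effect_size)

  ## group mean surfaces
  mu <- matrix(base, nl, 3, dimnames = list(locus_id, c("RA", "OA", "NL")))
  mu[ra$idx, "RA"] <- mu[ra$idx, "RA"] + ra$delta
  mu[nl_eff$idx, "NL"] <- mu[nl_eff$idx, "NL"] + nl_eff$delta
  mu <- pmin(pmax(mu, 0.01), 0.99)

  ## samples: per line, a shared line effect plus per-passage assay noise
  groups <- rep(names(config$group_sizes), config$group_sizes)
  line_ids <- unlist(lapply(names(config$group_sizes), function(g)
    sprintf("%s%02d", g, seq_len(config$group_sizes[[g]]))))
  z_mu <- stats::qlogis(mu)

  sheet <- list(); cols <- list()
  for (p in config$passages) cols[[as.character(p)]] <- list()
  for (li in seq_along(line_ids)) {
    g <- groups[li]
    z_line <- z_mu[, g] +
      stats::rnorm(nl, 0, logit_noise_sd(mu[, g], config$line_sd))
    draw_sample <- function(pass) {
      sd_b <- if (pass == 7)
        sqrt(config$assay_sd^2 + config$p7_extra_sd^2) else config$assay_sd
      stats::plogis(z_line +
        stats::rnorm(nl, 0, logit_noise_sd(mu[, g], sd_b)))
    }
    for (p in config$passages) {
      sid <- sprintf("%s_P%d", line_ids[li], p)
      cols[[as.character(p)]][[sid]] <- draw_sample(p)
      sheet[[length(sheet) + 1]] <- data.frame(
        sample_id = sid, phenotype = g, cell_line_id = line_ids[li],
        passage = p, replicate_label = NA_character_,
        stringsAsFactors = FALSE)
      if (p == 5 && config$p5_replicates) {
        rid <- sprintf("%s_P5rep", line_ids[li])
        cols[["5"]][[rid]] <- draw_sample(5)
        sheet[[length(sheet) + 1]] <- data.frame(
          sample_id = rid, phenotype = g, cell_line_id = line_ids[li],
          passage = 5, replicate_label = "rep1", stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, sheet)

  ## assemble matrices with missingness and detection p-values
  matrices <- list()
  for (p in as.character(config$passages)) {
    beta <- do.call(cbind, cols[[p]])
    rownames(beta) <- locus_id
    det <- matrix(stats::runif(length(beta), 0, 0.0009), nrow(beta),
                  ncol(beta), dimnames = dimnames(beta))
    fail <- stats::runif(length(beta)) < config$det_fail_rate
    det[fail] <- stats::runif(sum(fail), 0.02, 0.5)
    miss <- stats::runif(length(beta)) < config$miss_rate
    beta[miss] <- NA; det[miss] <- NA
    matrices[[p]] <- BetaMatrix(beta, det)
  }

  ## truth tables
  loci_truth <- data.frame(
    locus_id, in_promoter,
    is_planted_dml = seq_len(nl) %in% ra$idx,
    planted_delta = 0, is_planted_nl = seq_len(nl) %in% nl_eff$idx,
    planted_nl_delta = 0, stringsAsFactors = FALSE)
  loci_truth$planted_delta[ra$idx] <- ra$delta
  loci_truth$planted_nl_delta[nl_eff$idx] <- nl_eff$delta
  dmg_genes <- sort(unique(gene_symbol[prom_gene[match(ra$idx, prom_idx)]]))
  genes_truth <- data.frame(gene_symbol,
                            is_planted_dmg = gene_symbol %in% dmg_genes,
                            stringsAsFactors = FALSE)

  ## gene-set database: planted pathways concentrate planted DMG genes
  pw_id <- sprintf("pw%03d", seq_len(config$n_pathways))
  planted_pw <- pw_id[seq_len(min(config$n_planted_pathways,
                                  config$n_pathways))]
  entries <- list()
  for (i in seq_len(config$n_pathways)) {
    sz <- config$genes_per_pathway
    if (pw_id[i] %in% planted_pw && length(dmg_genes) > 0) {
      n_dmg <- min(ceiling(config$planted_gene_frac * sz), length(dmg_genes))
      in_g <- sample(dmg_genes, n_dmg)
      out_g <- sample(setdiff(gene_symbol, in_g), sz - n_dmg)
      gs <- c(in_g, out_g)
    } else {
      gs <- sample(gene_symbol, sz)
    }
    entries[[pw_id[i]]] <- list(name = sprintf("Synthetic pathway %03d", i),
                                genes = sort(gs))
  }
  db <- structure(list(source = "KEGG", entries = entries),
                  class = "PathwayDB")
  pathways_truth <- data.frame(pathway_id = pw_id,
                               is_planted_enriched = pw_id %in% planted_pw,
                               stringsAsFactors = FALSE)

  signature <- locus_id[sort(c(ra$idx, nl_eff$idx))]

  ## write everything
  paths <- NULL
  if (write) {
  paths <- list(sheet = file.path(dir, "sample_sheet.csv"),
                annotation = file.path(dir, "cpg_annotation.tsv"),
                models = file.path(dir, "gene_models.tsv"),
                gmt = file.path(dir, "pathways.gmt"),
                signature = file.path(dir, "signature.txt"),
                loci_truth = file.path(dir, "truth_loci.tsv"),
                genes_truth = file.path(dir, "truth_genes.tsv"),
                pathways_truth = file.path(dir, "truth_pathways.tsv"))
  write_sample_sheet(sheet, paths$sheet)
  write_cpg_annotation(annotation, paths$annotation)
  write_gene_models(models[, c("gene_symbol", "transcript_id", "chromosome",
                               "strand", "txStart", "txEnd")], paths$models)
  write_gmt(db, paths$gmt)
  write_signature(signature, paths$signature)
  utils::write.table(loci_truth, paths$loci_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(genes_truth, paths$genes_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pathways_truth, paths$pathways_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (p in names(matrices)) {
    bp <- file.path(dir, sprintf("beta_P%s.tsv", p))
    dp <- file.path(dir, sprintf("detection_P%s.tsv", p))
    write_beta_matrix(matrices[[p]], bp, dp)
    paths[[sprintf("beta_P%s", p)]] <- bp
    paths[[sprintf("detection_P%s", p)]] <- dp
  }
  }

  invisible(list(paths = paths,
                 truth = list(loci = loci_truth, genes = genes_truth,
                              pathways = pathways_truth),
                 matrices = matrices, sheet = sheet,
                 annotation = annotation, models = models, db = db,
                 signature = signature, config = config))
}

#' Expected inter-passage correlation ordering implied by a configuration
#'
#' Maps the configured noise ladder to the expected ranking of
#' inter-passage Spearman correlations: a passage pair's combined assay
#' noise determines its expected rho, so pairs involving passage 7 (which
#' carries `p7_extra_sd`) are expected to correlate less than P3-P5 when
#' that extra noise is positive, and all pairs are exchangeable when it is
#' zero.
#'
#' @param config a [sim_config()] with >= 2 passages.
#' @return data.frame with `pair`, `combined_sd` (root-sum-square of the
#'   two samples' assay SDs) and `expected_rank` (1 = highest expected
#'   rho; ties share a rank).
#' @export
passage_correlation_of <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (length(config$passages) < 2) stop("need >= 2 passages")
  sd_of <- function(p) if (p == 7)
    sqrt(config$assay_sd^2 + config$p7_extra_sd^2) else config$assay_sd
  pairs <- utils::combn(config$passages, 2, simplify = FALSE)
  combined <- vapply(pairs, function(pr)
    sqrt(sd_of(pr[1])^2 + sd_of(pr[2])^2), numeric(1))
  data.frame(
    pair = vapply(pairs, function(pr) paste0("P", pr[1], "-P", pr[2]),
                  character(1)),
    combined_sd = combined,
    expected_rank = rank(combined, ties.method = "min"))
}
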