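#' Build the five phenotype comparison plans
#'
#' Given a sample sheet and a passage, constructs the three primitive
#' two-group comparisons (RA vs OA; RA vs NL; RA vs the pooled OA+NL group)
#' and the two derived gene-set unions: `RA_vs_OA_or_NL` (DMGs significant
#' in either RA vs OA or RA vs NL) and `combined`
#' (RA vs (OA or NL) or (OA+NL)).
#'
#' @param sheet sample sheet data.frame (see [read_sample_sheet()]).
#' @param passage passage number whose samples enter the comparisons.
#' @return Named list of plans; primitive plans carry `group_a`/`group_b`
#'   sample-id vectors (and `usable`, FALSE when a group has < 3 samples),
#'   derived plans carry `derivation`, a character vector of plan names to
#'   union.
#' @export
build_plans <- function(sheet, passage) {
  s <- sheet[sheet$passage == passage & is.na(sheet$replicate_label), ]
  if (nrow(s) == 0) s <- sheet[sheet$passage == passage, ]
  pheno <- split(s$sample_id, factor(s$phenotype, c("RA", "OA", "NL")))
  missing <- names(pheno)[vapply(pheno, length, integer(1)) == 0]
  if (length(missing))
    stop("phenotype(s) absent at passage ", passage, ": ",
         paste(missing, collapse = ", "))
  prim <- function(a, b) list(group_a = a, group_b = b,
                              usable = length(a) >= 3 && length(b) >= 3)
  plans <- list(
    RA_vs_OA = prim(pheno$RA, pheno$OA),
    RA_vs_NL = prim(pheno$RA, pheno$NL),
    `RA_vs_OA+NL` = prim(pheno$RA, c(pheno$OA, pheno$NL)),
    RA_vs_OA_or_NL = list(derivation = c("RA_vs_OA", "RA_vs_NL")),
    combined = list(derivation = c("RA_vs_OA", "RA_vs_NL", "RA_vs_OA+NL"))
  )
  plans
}

#' Union DMG sets at the gene level
#'
#' Genes are pooled across the referenced sets; a gene's status is merged so
#' that conflicting directions (or any parent `mixed`) yield `mixed`.
#' Supporting loci are concatenated and deduplicated. Provenance (which
#' parent contributed each gene) is kept in `$provenance`.
#'
#' @param named_sets named list of `DMGSet` objects.
#' @param expression character vector of set names to union.
#' @param comparison_name label for the result.
#' @return A `DMGSet` with a `provenance` element (gene -> parent names).
#' @export
combine_dmg_sets <- function(named_sets, expression,
                             comparison_name = "union") {
  undef <- setdiff(expression, names(named_sets))
  if (length(undef)) stop("undefined set name(s): ",
                          paste(undef, collapse = ", "))
  genes <- character(0); supporting <- list(); provenance <- list()
  for (nm in expression) {
    s <- named_sets[[nm]]
    for (g in names(s$genes)) {
      if (is.null(supporting[[g]])) {
        genes[g] <- s$genes[[g]]
        supporting[[g]] <- s$supporting[[g]]
        provenance[[g]] <- nm
      } else {
        supporting[[g]] <- unique(rbind(supporting[[g]], s$supporting[[g]]))
        provenance[[g]] <- c(provenance[[g]], nm)
        dirs <- unique(supporting[[g]]$direction)
        genes[g] <- if (length(dirs) > 1) "mixed" else dirs
        if (s$genes[[g]] == "mixed" || genes[g] == "mixed")
          genes[g] <- "mixed"
      }
    }
  }
  structure(list(comparison_name = comparison_name, genes = genes,
                 supporting = supporting, provenance = provenance),
            class = "DMGSet")
}
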