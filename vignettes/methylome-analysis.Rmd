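---
title: "Methods: differential methylation, promoter DMGs, enrichment and passage stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation, promoter DMGs, enrichment and passage stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flsmethylome)
```

This vignette documents the statistical model behind each stage of the
package, the parameters that matter, the design choices made where the
conventions were genuinely open, and what the synthetic cohort does and
does not emulate.

## Data model

The central object is a `BetaMatrix`: loci × samples methylation
fractions (beta values, β = M/(M+U) intensities on an Illumina-style
array) in [0,1], with an optional parallel matrix of per-value detection
*p*-values and `NA` for missing measurements. Two detection thresholds
play different roles and are implemented as separate stages:

* **0.001 — dataset QC** (`qc_filter_loci()`): any locus with at least
  one sample whose detection *p* exceeds 0.001 is dropped from the
  dataset before analysis.
* **0.01 — per-value masking** (`group_values()`, inside `call_dml()`):
  during differential testing, individual values with detection
  *p* > 0.01 are excluded, like missing values.

The order (QC first, then masking) is configurable in
`pipeline_config()` because the two rules originate in different stages
of array processing; both defaults follow standard chip practice.

## Differential methylation

For a locus with usable values in groups A and B, `call_dml()` computes
Welch's statistic

$$t = \frac{\bar\beta_A - \bar\beta_B}
          {\sqrt{s_A^2/n_A + s_B^2/n_B}},$$

with Welch–Satterthwaite degrees of freedom and a two-sided *p*-value.
Two-sidedness is a deliberate choice: both hyper- and hypomethylation
are biologically expected. A locus is skipped (not tested, excluded from
the multiplicity burden) when either group retains fewer than
`min_per_group = 3` values. Degenerate inputs follow explicit
conventions: two constant equal groups give *t* = 0, *p* = 1; constant
but unequal groups are a noiseless difference, *p* = 0.

*q*-values follow the Storey procedure: with
$\hat\pi_0$ the estimated null proportion, the step-up
$q_{(i)} = \min_{j \ge i}\, \hat\pi_0\, m\, p_{(j)}/j$ capped at 1.
$\hat\pi_0$ uses the smoother method — $\hat\pi_0(\lambda) =
\#\{p > \lambda\}/(m(1-\lambda))$ on the grid
$\lambda = 0.05, 0.10, \ldots, 0.95$, a 3-df smoothing spline evaluated
at $\lambda = 0.95$, clamped to (0,1]. For *m* < 100 the smoother is
unstable, so $\hat\pi_0 = 1$ (the Benjamini–Hochberg step-up,
conservative); this applies in practice to pathway-level *q*-values,
where *m* is the number of tested gene sets. *q*-values are computed per
comparison over its tested loci only: skipped loci never had *p*-values,
so they cannot contribute to *m*.

A locus is a **DML** when *q* < 0.05 **and** |Δβ| > 0.1, strict
inequalities, with Δβ = mean(A) − mean(B) and A = RA in all shipped
configurations; `hyper` means higher methylation in RA.

## Promoter windows and DMGs

The promoter is the 3 kb interval −2500…+500 bp around the TSS. Offsets
are applied in the direction of transcription (on the − strand the
window is [TSS−500, TSS+2500] in genomic coordinates): the upstream /
downstream asymmetry of the window only makes sense relative to
transcription. Whether a published genomic analysis oriented by strand
or used fixed genomic offsets is rarely stated; orientation is the
conventional reading and the window rule is configurable (`up`, `down`).
The window includes both ends — 3001 positions; the ±1 inclusivity is a
documented choice. All coordinates are 1-based inclusive internally;
UCSC 0-based half-open inputs (refFlat, BED) are converted at the
boundary, so TSS = txStart+1 on + and txEnd on −.

A gene is a **DMG** when any transcript's window contains ≥ 1 DML
(any-transcript rule for multi-isoform genes). Its status is `hyper` /
`hypo` when all supporting DMLs agree, `mixed` otherwise. Comparison
sets are combined at the **gene level** — "significant in either" is
defined over DMGs, not loci — and *q*-values are not recomputed after a
union, since the union is of already-called sets.

## Over-representation

With background N = (union of database genes) ∩ (genes covered by the
array), pathway coverage K, DMG count n = |DMG ∩ background| and overlap
k, the enrichment factor is EF = (k/K)/(n/N), and the *p*-value is the
inclusive upper tail P(X ≥ k) of the hypergeometric distribution —
the standard over-representation convention. Restricting *n* to the
covered background (rather than all DMGs) matches the background
definition; the alternative is exposed as `restrict_n = FALSE`.
*q*-values are computed within each database (KEGG separately from GO);
GO namespaces are pooled in one run by default. The printed percentage
is 100·k/K rounded half-even to one decimal. Results sort by (q, EF
descending).

## Passage stability

Per cell line, Spearman correlations between passages are computed on
the signature loci with pairwise-complete observations (≥ 3 complete
pairs, else reported missing) and averaged across lines per passage
pair; replicate correlations are computed within the same cell line
only. Δβ histograms use fixed bins of width 0.01 with edges at
multiples of the bin width over [−1,1], left-closed, reported as
densities count/(total·binwidth) so bar areas sum to one. Clustering
multiplies β by 100, computes Euclidean distances with
pairwise-complete handling rescaled proportionally to the full
dimensionality (`stats::dist`'s convention — chosen over imputation or
dropping because it does not bias sparse pairs downward), and
agglomerates both axes by complete linkage. A sample pair sharing no
observed locus is an error naming the pair, not a silent NA.

## The synthetic cohort

`simulate_cohort()` generates the full study structure so that every
stage has ground truth:

* **Design.** 11 RA / 11 OA / 6 NL cell lines (defaults), each at
  passages 3, 5, 7, optionally with technical replicates at passage 5.
* **Baselines.** Per-locus means from an equal mixture of
  Beta(2, 18) (mode near 0.1) and Beta(17, 3) (mode near 0.85),
  reproducing the bimodal marginal distribution of array methylomes.
* **Noise.** Per line, a line effect; per sample, assay noise — both
  applied on the logit scale and inverse-transformed, which keeps
  values in (0,1) without boundary pile-up. The logit-scale SD is
  scaled by the delta method (divided by max(μ(1−μ), 0.1)) so the
  beta-scale SD is approximately the configured value in the informative
  mid-range and smaller near the boundaries, as on real arrays.
  Defaults `line_sd = 0.05`, `assay_sd = 0.05`.
* **Passage-7 noise.** `p7_extra_sd = 0.08` adds senescence-related
  drift. The value is calibrated from the study's reported correlation
  ladder: inter-passage Spearman ≈ 0.94 for P3–P5 falling to ≈ 0.88 for
  P3–P7 implies the P7 noise variance is roughly triple the assay
  variance, i.e. an extra SD ≈ 1.5 × assay_sd.
* **Planted effects.** A fraction `frac_dml = 0.02` of promoter loci
  shifts the RA group mean by ±`effect_size` (0.3), balanced hyper/hypo
  wherever the baseline leaves room. A disjoint set (`nl_frac`,
  `nl_effect_size = 0.2`) shifts the NL group: real normal lines differ
  from diseased lines, and without an NL-specific component a
  three-group clustering of the signature could never separate OA from
  NL. The planted effect of 0.3 with assay SD 0.05 represents the
  clearly-differentiated loci the DML thresholds (|Δβ| > 0.1) are
  designed to catch.
* **Signature.** The emitted signature list is the union of RA-effect
  and NL-effect loci — the synthetic analogue of a previously derived
  discriminating CpG set.
* **Artefacts.** `miss_rate = 0.01` of cells are missing;
  `det_fail_rate = 0.001` of values draw detection *p* in (0.02, 0.5)
  (failing both thresholds), the rest below 0.001. Detection failures
  on arrays are rare events, well under a percent of values.
* **Genome and database.** One synthetic chromosome, genes every 10 kb
  with alternating strands, so promoter windows never overlap and truth
  tables are unambiguous. Pathways of 25 genes; two planted pathways
  draw 60% of their members from planted DMG genes, the rest uniformly.

Identical seeds give byte-identical output files.

**What passing tests do and do not show.** The generator emulates group
structure, bimodality, noise hierarchy, missingness and detection
failure, but not Infinium I/II probe-type chemistry, batch effects,
copy-number or SNP artefacts, spatially correlated CpGs, or
non-Gaussian line effects. Recovery results on synthetic cohorts
therefore validate the statistical machinery — thresholds, multiplicity
handling, promoter mapping, enrichment arithmetic — not robustness to
array-specific artefacts, which the upstream normalisation is assumed
to have handled.

## Problem sizes and determinism

The shipped analyses and tests use 20,000-locus cohorts for recovery and
null studies (10 seeds each) and 2,000-locus, 3/3/3-line cohorts for
stability properties (20 seeds) — large enough that planted effects are
comfortably inside the power envelope of 11-vs-11 and 11-vs-17
comparisons while the full suite stays fast. Recovery under the default
conditions is ≈ 97% of planted loci at an empirical FDR below 1%, and
the two planted pathways rank first by *q* in every seed tested.

The pipeline (`run_pipeline()`) writes a manifest with md5 hashes of all
inputs and outputs, the seed, thresholds, and per-stage counts (tested /
skipped / DML / DMG / significant pathways per comparison); identical
configurations and seeds give identical manifests.

## Known limitations

* The published cohort-scale counts (thousands of DMGs; twenty
  significant KEGG pathways of 271) depend on the full 28-line dataset,
  which is not publicly deposited in full; they are not reproduction
  targets of the synthetic analyses.
* Storey π₀ estimation with the smoother is unreliable for small *m*;
  the π₀ = 1 fallback makes pathway-level *q*-values conservative for
  small databases.
* Union sets deduplicate at the gene level; a locus-level "combined"
  definition would differ only when the same gene is supported by
  different loci in different comparisons, which does not change
  membership, only the supporting lists.
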