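---
title: "Linking stroma-induced chromatin accessibility to expression and the Sigma-ASI classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking stroma-induced chromatin accessibility to expression and the Sigma-ASI classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromasig)
```

## The scientific problem

Multiple myeloma cells interact with bone marrow stromal cells (BMSCs), and
those interactions remodel the tumor cells' chromatin: some regions gain
accessibility (euchromatin formation), others lose it. When a gained region
is a cis-regulatory element (CRE) — an enhancer or promoter — the change can
drive transcription of nearby genes, and the induced expression program has
clinical consequences: worse survival, early therapeutic resistance, and
dissemination outside the bone marrow.

`stromasig` implements that chain of inference as a reusable pipeline:

1. **Differential counts** — test ATAC-seq peak counts and RNA-seq gene
   counts between co-culture and control conditions (negative-binomial Wald
   test, Benjamini–Hochberg FDR).
2. **CRE–gene linking** — assign differentially accessible regions to one
   or two proximal target genes, never crossing a topologically associating
   domain (TAD) boundary.
3. **Integration** — derive the *concordant* gene set (up-regulated genes
   whose linked CREs gained accessibility) and quantify the association by
   Fisher's exact over-representation test and a hypergeometric overlap
   test.
4. **Signature selection** — find genes independently associated with
   survival in a patient cohort by the consensus of forward and backward
   stepwise Cox proportional-hazards selection.
5. **Sigma-ASI score** — summarize a 10-gene signature (5 adverse, 5
   favorable) per patient as a decile sum, dichotomize into ASI+/ASI−, and
   validate against survival and early therapeutic resistance.
6. **Enrichment** — weighted Kolmogorov–Smirnov gene-set enrichment with
   phenotype-permutation significance and family-wise error correction,
   for testing signature concordance between two cell populations.

A synthetic-data module generates genome annotations, coupled ATAC/RNA
count matrices and patient cohorts with *planted* ground truth, so every
stage — and the pipeline end to end — is testable without any external
download.

## Coordinate and data conventions

All genomic coordinates are 0-based half-open (BED convention). A position
sitting exactly on a TAD boundary belongs to the TAD on its right. Strand
affects only the definition of a gene's TSS; CREs are strandless, and
distances are measured from the CRE interval midpoint to the TSS.

Count matrices are integer feature × sample matrices with a two-level
condition map (`control` / `coculture`). Patient cohorts carry a
gene × patient expression matrix, survival time (months) and event
indicator, an optional binary early-resistance response, and a clinical
covariate table.

Every stochastic operation takes an explicit seed and leaves the global
RNG state untouched, so identical seeds give byte-identical outputs.

## The synthetic-data generator

`generate_genome_annotation()` tiles each chromosome with non-overlapping
TADs (random breakpoints, minimum width 50 kb) and places genes and CREs
uniformly. `generate_coculture_experiment()` draws counts from a negative
binomial parameterized by mean `mu` and dispersion `alpha` (variance
`mu + alpha * mu^2`), the standard count model for both assays. Its
defaults are the conditions used throughout the package's tests:

* 3 biological replicates per condition — matching a three-cell-line
  co-culture design;
* baseline mean 100 — a typical well-covered ATAC peak / moderately
  expressed gene;
* dispersion 0.05 — cell-line-level biological variability;
* 10% of CREs planted with a +2 log2 fold change in the co-culture
  condition — strong stromal induction;
* coupling 1.0 — every planted CRE transmits its effect to the nearest
  gene in the same TAD within 1 Mb, and those CRE–gene pairs form the
  planted truth ledger.

Unplanted features keep a constant baseline mean, so per-feature sample
means have a known sampling distribution the tests can check directly.

`generate_patient_cohort()` draws expression as standard normal per gene
(the z-score scale the selection stage uses), survival from an exponential
(or Weibull) proportional-hazards model whose log hazard is linear in the
expression of chosen genes, independent exponential censoring calibrated
to a target censoring fraction, an early-resistance outcome from a
logistic model, and myeloma-like binary covariates (ISS stage 3, elevated
LDH, high-risk translocation, del17p, gain1q) independent of expression.
The baseline hazard of 0.02/month puts median survival near 35 months,
realistic for newly diagnosed myeloma.

What the generator does *not* emulate: mean–dispersion trends across
features, GC or fragment-length biases, correlated expression between
genes, batch effects, informative censoring, or covariates correlated
with expression. Passing tests therefore demonstrate the pipeline's
statistical machinery under its stated model, not robustness to every
artifact of real sequencing data.

## The differential count test

For each feature, counts are normalized by median-of-ratios size factors
(geometric mean across samples computed over features with no zeros;
factors rescaled to geometric mean 1). The log2 fold change uses a
pseudo-count of 0.5. The Wald statistic divides the log2 fold change by a
delta-method standard error built from the NB variance function, and
features with mean normalized count below 10 are not tested (their p and
FDR are reported missing) to avoid degenerate dispersion estimates.

The dispersion is where small designs bite. With 3 replicates per
condition a raw per-feature method-of-moments estimate is so noisy that a
normal-reference Wald test rejects ~11% of true nulls at the 5% level,
while referring the same statistic to a t with 4 degrees of freedom
restores calibration but caps the attainable p-values so severely that
3-fold effects no longer clear a Benjamini–Hochberg threshold. The
package therefore moderates: each feature's moment estimate is shrunk
toward the across-feature 5%-trimmed mean with prior weight
`prior_df = 20` pseudo-degrees of freedom, and the statistic is referred
to a t with `n1 + n2 − 2 + prior_df` degrees of freedom. This is the same
information-sharing idea limma and DESeq2 rely on, in method-of-moments
form. In pilot simulations at the 3v3, mean-100, dispersion-0.05 design
point this keeps the null rejection rate at 4.3–6.3% across repeats while
detecting >99% of 3-fold changes at FDR < 0.05. Setting `prior_df = 0`
recovers the raw per-feature estimator. The dispersion floor is 1e-8.

Thresholds: FDR < 0.050 for accessibility and expression alike, with no
fold-change cutoff. Replicates are pooled within condition; cell lines
are not modeled as blocks.

## CRE–gene linking and integration

`assign_target_genes()` keeps, per region, the `max_genes = 2` nearest
genes whose TSS lies within `max_distance = 1 Mb` (the GREAT-style
default extension) of the region midpoint *and* inside the same TAD as
that midpoint. Distance ties break lexicographically by gene id for
determinism. Regions whose midpoint falls in an inter-TAD gap are skipped
with a warning; regions with no eligible gene simply yield no link, and
the attrition is visible to the caller.

"De novo accessibility" is interpreted as a significant accessibility
*increase* (FDR < threshold, log2FC > 0), since a count-based framework
has no peak presence/absence concept. Genes with several CREs need only
one concordant CRE — no dosage requirement. The over-representation 2×2
table cross-classifies up-regulation against linkage to at least one CRE
with *altered* (either direction) accessibility, over the universe of
tested genes; the hypergeometric overlap test defaults to that same
tested-gene universe, a choice the caller can override by passing counts
directly. Distance–effect summaries use per-bin medians, the package-wide
preference for robust central tendency.

## Stepwise consensus selection

Candidate gene expression is standardized per gene before fitting, so
coefficients are per standard deviation. Forward selection adds, at each
step, the candidate with the smallest likelihood-ratio p-value if it is
below `p_enter = 0.200`; backward elimination starts from the full model
and removes the gene with the largest likelihood-ratio p-value while it
is at or above `p_remove = 0.200`. Likelihood-ratio rather than Wald
p-values drive the stepping because they are stable for near-boundary
coefficients. The consensus is the intersection of the two selections,
refit jointly; hazard ratio direction in the joint model labels each gene
adverse (HR > 1) or favorable (HR < 1). Ties in stepping p-values break
by gene id, making selection invariant to candidate ordering. If the full
model is unfittable (more genes than events, or non-convergence) the
forward-only result is returned, flagged non-consensus, with a warning.
Selection uses genes only by default; clinical covariates enter at the
validation stage instead.

The cohort object carries one time/event pair; the `endpoint` argument
records which endpoint ("pfs" by default, "os" by flag) those columns
represent rather than switching between two stored endpoints.

## The Sigma-ASI score

Each of the 10 signature genes is decile-transformed *within the scoring
cohort* (cross-sectional, not against an external reference): deciles are
cut at the empirical quantiles q₀.₁…q₀.₉, a value at or below q₀.₁ maps
to decile 1 and above q₀.₉ to decile 10, and tied values always share a
decile — which makes the score invariant under any strictly monotone
transform of the expression scale.

With decile d, the default contribution rule is **(d − 1) per adverse
gene plus (10 − d) per favorable gene**, summed over the 10 genes. This
yields the documented anchors exactly: a patient with every adverse gene
at decile 10 and every favorable gene at decile 1 scores 90, and the
mirrored patient scores 0. A literal variant that adds the raw decile d
for adverse genes is available behind `literal = TRUE`; its range is
5–95. The two cannot both hold, and the package defaults to the rule that
reproduces the 0 and 90 anchor values, since those anchors pin down the
intended scale.

Dichotomization calls a patient ASI+ when Sigma-ASI ≥ 50 (boundary
inclusive), a cutoff chosen to give roughly a 70/30 standard-/high-risk
split; on a cohort where expression is exchangeable across genes the
empirical 70th-percentile cutoff reproduces that split by construction,
and the fixed-50 split fraction is reported rather than asserted.

Validation is standard survival and categorical machinery: Kaplan–Meier
curves, the log-rank test, Cox models for the ASI+ hazard ratio with Wald
confidence intervals (unadjusted and covariate-adjusted, Efron tie
handling), Fisher's exact test and logistic regression for early
therapeutic resistance (stable or progressive disease three months after
starting first-line treatment). Degenerate inputs take explicit paths: a
constant outcome yields Fisher p = 1 with a warning and no logistic fit;
identical groups yield a log-rank statistic of 0 and p = 1.

## Enrichment

`enrichment_score()` implements the weighted KS running sum: hits
increment by |stat|^weight normalized over in-set statistics, misses
decrement by 1/(N − |set|); the ES is the signed extremum. With weight 0
this is the classic KS statistic, bounded in [−1, 1], and the walk closes
at 0 by construction. `gsea_significance()` ranks genes by the
signal-to-noise ratio between the two phenotypes (first factor level
minus second) with the conventional standard-deviation floors
(0.2 × |mean|, minimum 0.2), then permutes the *phenotype labels* — the
recommended mode for two-class designs with many samples — to build the
null. NES divides the ES by the mean |null ES| of matching sign; the
nominal p is the same-sign null tail; the FWER p is the fraction of
permutations whose most extreme normalized null ES beats |NES|, floored
at the nominal p because a family-wise rate cannot undercut the per-set
rate. Ranking ties break by gene id. A helper subsamples the larger of
two populations to balance group sizes, deterministically for a fixed
seed.

## Problem sizes used in the test suite

The packaged tests exercise: a 1-chromosome, 10-TAD, 100-gene, 500-CRE
genome for the end-to-end recovery run; 1,000 features at 3 vs 3 for null
calibration and for power at a 3-fold change; 50 replicate cohorts of 600
patients (two planted genes, |log HR| = 0.5, among 10 candidates) for
selection recovery; and a 1,000-gene, 200 vs 200-cell matrix with a 1-SD
shift in a 68-gene set at 1,000 permutations for enrichment. These sizes
make the Monte-Carlo assertions stable while keeping the whole suite
around a minute of runtime.

## Known limitations

* The differential module fits no covariates and no shrinkage of fold
  changes; it is a calibrated stand-in for DESeq2/DiffBind-style
  analyses, not a reimplementation.
* TADs are inputs; the package does not derive them from Hi-C.
* The concordant-set universe (tested genes) is a convention; other
  universes change the overlap p-value and are the caller's choice.
* The stepwise procedure inherits the usual caveats of stepwise
  selection (optimism, instability at weak effects); the package reports
  the null selection rate rather than pretending it is zero.
* No multi-set GSEA database runs, no single-cell preprocessing, and no
  read-level simulation.
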