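---
title: "Scoring BRCAness across cancer types: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring BRCAness across cancer types: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcaness)
```

## The problem

BRCAness is the tumor phenotype in which homologous-recombination (HR)
repair is defective through lesions in HR-related genes other than BRCA1/2.
Because PARP-inhibitor (PARPi) therapy is synthetically lethal with
HR deficiency, tumors with BRCAness features are candidate PARPi targets
even when BRCA1/2 themselves are intact. This package quantifies BRCAness
at the cancer-type level: it computes six features of a curated 40-gene
BRCAness panel from cohort-style multi-omics tables, normalizes each
feature against breast and ovarian reference cohorts (the cancers where
BRCA1/2-driven PARPi response is established), and ranks cancer types by
the composite score.

The six features, per cancer type, are:

1. **Somatic PLP carrier frequency** -- sum over panel genes of the
   fraction of tumors carrying at least one somatic pathogenic or
   likely-pathogenic (PLP) variant in the gene.
2. **Germline PLP carrier frequency** -- the same for germline calls.
3. **Homozygous-deletion frequency** -- sum over panel genes of the
   fraction of tumors with a GISTIC gene-level code of exactly -2.
4. **Promoter methylation load** -- sum over panel genes of the mean
   promoter beta value (probes within +/- 10 kb of the TSS).
5. **Differential expression** -- number of panel genes differentially
   expressed tumor vs normal (Wilcoxon rank-sum, BH-adjusted p < 0.01,
   at least two-fold change).
6. **Prognosis** -- number of panel genes whose median-split expression
   groups differ in overall survival (two-sided log-rank p < 0.05).

Each feature is divided by its value in the first reference cohort and in
the second, giving 12 normalized columns in which the references score
exactly 1. The composite Sum adds the 12 columns (missing features
contribute 0), and a cancer type qualifies as a BRCAness candidate when its
Sum strictly exceeds the reference Sum (12.0 when all six features are
defined).

## Data model

All readers live in `load_cohort()` and expect tab-delimited tables:
MAF-dialect variant calls (1-based, fully closed coordinates) with an
`origin` column separating somatic from germline calls; a pathogenicity
catalog with ClinVar-style labels (only "Pathogenic"/"Likely pathogenic"
ClinVar rows and "Pathogenic" COSMIC rows are retained); a gene x sample
GISTIC code matrix; a probe x sample beta matrix with a probe manifest; a
gene x sample log2(norm+1) expression matrix; a clinical table with
overall-survival days and event indicators; and a sample map carrying each
sample's cancer type and tumor/normal flag. Cancer-type labels are free
strings -- nothing in the pipeline hard-codes a label set. Loaders never
drop rows silently: rows are accepted, rejected or flagged, with counts
logged, and samples missing from the sample map are a hard validation
error.

The default gene panel (42 symbols: 40 BRCAness genes plus the BRCA1/2
references) ships with approximate GRCh38 TSS coordinates. The annotation
declares its build explicitly because promoter windows are
coordinate-sensitive; supply your own table through
`load_default_panel(path=)` to use another build. Gene symbols are matched
case-insensitively with no alias resolution.

## Stage-level choices

**PLP matching.** Variants are first filtered to passing, non-silent calls
(the standard MAF non-silent classification set, configurable). Matching
against the catalog is allele-level on (chrom, pos, ref, alt) after
minimal-representation normalization (shared suffix trimmed, then shared
prefix with the position advanced). Full left-alignment against a genome
sequence is out of scope; minimal representation already makes differently
padded indel spellings compare equal. Catalog keys are deduplicated across
sources, so a variant present in both ClinVar and COSMIC matches once.
Carrier frequencies count distinct samples, not variant rows, and the
denominator is all tumor samples of the type. A pan-cancer pooled
aggregate is reported separately and labeled as such, since per-type and
pooled prevalence answer different questions.

**Correlation screens.** Pearson's r across cancer types
(pairwise-complete cells, at least 3), two-sided p from the t transform on
n - 2 degrees of freedom. The significance rule is p < 0.05 plus an |r|
threshold: 0.5 for variant frequencies, 0.4 for deletion frequencies.
Zero-variance vectors give an undefined (never significant) result.

**Promoter methylation.** "Within 10 kb surrounding the TSS" is read as
TSS +/- 10 kb with an inclusive boundary; the half-window is a config knob
(`tss_window`) for a stricter reading. A gene's per-type promoter level is
the mean beta over (window probes x tumor samples); genes with no window
probes are missing, never zero. Hypermethylation is a strict
`mean > 0.3`: a mean of exactly 0.3 is not called. For the
methylation-expression association the aggregation level matters: the
per-sample promoter beta (mean over window probes for that sample) is
correlated with that sample's expression, because only sample-level
aggregation yields a correlation that can detect silencing; calls are
"silencing" at r <= -0.5 and "enhancing" at r >= 0.5.

**Differential expression.** The Wilcoxon rank-sum p is exact (full null
distribution) when the combined sample size is at most 12 without ties,
and the tie-corrected, continuity-corrected normal approximation
otherwise. BH adjustment is applied within each cancer type across the
panel genes -- DEGs are defined per cancer type, so the type is the family.
Fold change defaults to the ratio of linearized means, mean(2^x - 1),
because inputs are log2(norm+1); a difference-of-log2-means mode is
config-selectable (`fold_change_scale`). "At least two-fold" is inclusive
in both directions. Cancer types with fewer than 5 normal samples are
skipped entirely, making the expression feature missing (not zero) for
them.

**Survival.** Patients are split at each gene's median expression; values
exactly at the median go to the low group (a documented, tested tie rule
-- the even/odd behavior of the median makes some rule necessary).
Kaplan-Meier curves and the two-sided log-rank test come from the survival
package; the hazard ratio is computed from the log-rank O/E quantities,
HR = (O_high/E_high)/(O_low/E_low) with CI
exp(log HR +/- 1.96 sqrt(1/E_high + 1/E_low)). This O/E estimator is
self-contained (no iterative model fit); a proportional-hazards regression
is deliberately out of scope. Survival p-values are not multiplicity
adjusted -- the risky-gene count is a raw p < 0.05 screening feature, and
should be read as such. "Risky count" defaults to any significant gene;
`risky_mode = "hr_gt_1"` restricts it to genes where high expression is
the hazard. Patient stratification uses hierarchical clustering (Euclidean
distance, average linkage) cut at k = 2, with groups labeled lower/higher
by mean panel expression; the clustering method is a documented choice
among several defensible ones and is isolated in `stratify_patients()`.

**Scoring.** Qualification is `Sum > reference Sum` rather than "every
normalized column >= 1": the published composite-score table shipped as a
worked example retains rows with individual columns below 1, so the
column-wise rule cannot be what produced it; the stricter rule remains
available (`qualify_rule = "all_columns"`). Missing features contribute 0
to the Sum -- the worked-example rows with missing cells sum exactly under
this convention. Frequency features aggregate per-gene frequencies by
summation over the 40 non-reference genes; normalization happens after
aggregation. Re-running assemble/normalize/score on the same inputs is
bit-reproducible.

## The synthetic cohort generator

`simulation_design()` plants, per gene x cancer type: PLP carrier
probabilities (applied independently to the somatic and germline origins),
homozygous-deletion probabilities, mean promoter betas, tumor-vs-normal
log2 expression shifts, methylation-to-expression silencing couplings, and
hazard ratios. Survival is exponential with the per-sample rate multiplied
by the planted hazard for every gene whose expression exceeds its
within-type median, with independent uniform censoring -- the simplest
model whose true hazard ratio equals the rate ratio. Betas are Gaussian
around the planted mean, clipped to [0.01, 0.99] (keeping betas valid
without a full beta-distribution model; at low means the clipping biases
the mean upward by well under 0.01). Each gene gets three probes inside
its promoter window and one outside, so window logic is exercised.
Background variants span silent and non-silent classifications and
occasionally fail the FILTER, so filter logic is exercised. Identical
design + seed gives identical cohorts.

`brcaness_design()` encodes the default study conditions used throughout
the tests: ten cancer types of 60 tumors and 10 normals each -- two
references with moderate signal in a 10-gene core (carrier frequency 0.05,
deletion 0.03, promoter beta 0.40, log2 shift -1.8, hazard 2.2), two
"BRCAness-high" types with broader and stronger signal over 20 genes
(0.12 / 0.06 / 0.55 / -2.8 / 3.0), and six background types at low rates
(0.01 / 0.005 / 0.15 / 0 / 1). These magnitudes are chosen to resemble a
mid-sized cohort with clinically meaningful effect sizes: carrier
frequencies in the 1-12% range, deletion rates below 6%, promoter shifts
that cross the 0.3 hypermethylation cutoff only where planted, expression
shifts beyond two-fold, and hazards detectable at n = 60 but far from
deterministic. `null_design()` sets every effect to its null value for
calibration.

What the generator does *not* emulate: mutational signatures, copy-number
segment geometry, probe-level 450k artifacts, batch effects, correlated
genes, or non-proportional hazards. Passing tests therefore demonstrate
that the pipeline's estimators recover the parameters of this statistical
structure -- binomial carrier draws, Gaussian betas and expression,
exponential survival -- not that they are robust to everything real cohort
data contains.

## Validation strategy and problem sizes

The test suite checks every estimator against an independent oracle: the
exact Wilcoxon p against full enumeration of rank assignments for every
group-size split with combined n <= 12 (the exact two-sided p depends only
on the group sizes and the rank sum, so enumerating every attainable rank
sum covers all untied configurations); BH against its brute-force
definition on 1000 random vectors at 1e-12; Kaplan-Meier, log-rank and the
O/E hazard ratio against hand-computed product-limit and hypergeometric
tables (the 4-patient fixture has statistic 49/17 and HR exactly 19/5);
and Pearson r/p against the closed form at 1e-12.

Monte-Carlo checks use these sizes: hazard-ratio recovery within +/- 30%
of a true HR of 2 at 300 patients per arm over 200 simulations (with CI
coverage in [90%, 99%]); composite-rank recovery of the two planted
BRCAness-high types over 100 seeded cohorts at the default design; null
calibration of the log-rank screen over 1008 gene-type pairs (42 genes x
24 types, 100 patients each) with the p < 0.05 fraction required to land
in [0.03, 0.07]; and DEG false-positive rates over 200 null replicates
required to stay at or below the nominal 0.01. The whole suite runs in a
few minutes on one CPU.

One arithmetic note on the packaged published score table: most rows
re-sum exactly from their printed cells; rows printed at one decimal per
cell can accumulate up to about 0.2 of rounding residue over 12 cells
(e.g. the KICH row re-sums to 30.7 against a printed 30.5), so the
round-trip check on non-exact rows allows 0.25.

## Degenerate inputs and numerical conventions

* Empty variant files with valid headers load as zero-variant cohorts.
* A cancer type with no samples yields missing frequency cells, not zeros.
* All-identical expression values give a degenerate median split, which is
  skipped and logged, and a rank-sum p of 1 (no evidence of shift).
* Zero-variance vectors make correlations undefined, never significant.
* A reference cohort with a zero or missing feature makes normalization an
  error naming the feature -- under a fully null cohort the reference DEG
  count is legitimately zero, so composite scoring of null data requires
  neutralizing the count features (the tests do exactly that, and say so).
* Rounding of reported per-type means uses base R's round-half-to-even.
* Ranks break ties by table order so they always form a permutation.

## Limitations

The pipeline consumes gene-level GISTIC codes, pre-normalized betas and
expression; no segmentation, probe QC or batch correction is performed.
Allele matching without a reference genome cannot left-align indels across
repeat tracts. The risky-gene count is unadjusted for multiple testing by
design. The composite score weights all six features equally on the
reference-normalized scale; a feature with a tiny reference value can
dominate the Sum, which is inherent to this normalization and visible in
the worked example's germline column.
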