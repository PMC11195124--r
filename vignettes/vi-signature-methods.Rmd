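---
title: "Methods: the vascular-invasion gene-signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the vascular-invasion gene-signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`visig` implements a complete analysis pipeline for deriving and
stress-testing a vascular-invasion (VI) gene-expression signature in
stage I lung adenocarcinoma (LUAD). Because patient-level data of this
kind cannot be redistributed, the package pairs every analysis stage
with a synthetic-data generator that plants the structure the stage is
supposed to detect; all claims the package makes about itself are the
ones its test suite and `scripts/acceptance.R` actually compute.

## The statistical model, stage by stage

**Normalization and filtering.** Library sizes are normalized by the
trimmed mean of M-values (TMM, via edgeR), genes are kept when CPM > 1
in at least 10% of samples (`ceiling` rule at the boundary), and
samples whose quality score deviates more than 2 SD from the cohort
mean are dropped in a single pass — the mean and SD are not iteratively
re-estimated after exclusions, because one pass is all the exclusion
rule defines. Log2-CPM uses a library-proportional pseudo-count
(default 2); the pseudo-count is not specified by the protocol this
reimplements, so it is configurable and recorded with results.

**Differential expression.** Each gene is modeled as negative binomial
with log link and effective-library-size offset,
$\mathrm{Var}(y) = \mu + \phi\mu^2$. The tumor grade (LMP < NST < VI,
reference LMP) is the independent variable; VI-vs-LMP is the primary
contrast, tested per gene by a likelihood-ratio chi-square between the
full fit and a fit constrained to the orthocomplement of the contrast.
Lymphatic invasion can enter as a binary covariate, with its own
contrast. P-values are Benjamini–Hochberg adjusted; non-converging
genes are flagged and excluded from the FDR denominator.

**Dispersion moderation.** Per-gene dispersions maximize a weighted
combination of the gene's own Cox–Reid adjusted profile likelihood and
the average profile over all genes, with prior weight `prior_df = 10`
degrees of freedom against the gene's residual degrees of freedom. We
first implemented moderation as a fixed-weight average of *point
estimates* (weight 0.25 on the gene-wise estimate) and found it
indefensible: under realistic log-normal dispersion spread (sdlog 0.5),
it halves the dispersion of genuinely high-dispersion genes, and in
permutation experiments essentially every false discovery at FDR 0.05
was such a gene. The weighted-*likelihood* form lets a gene with clear
evidence keep its dispersion, restoring false-discovery control while
still stabilizing small cohorts. Likelihoods are evaluated on a
30-point log-dispersion grid spanning $[10^{-6}, 10]$ and maximized
through interpolating splines, one GLM refit per grid point.

**Signature clustering.** Genes significant at FDR < 0.01 are z-scored
per gene, and Ward (`ward.D2`) hierarchical clustering on Euclidean
distances is cut at k = 4. Per-gene z-scoring before the distance is a
choice the protocol leaves implicit (its heatmaps are row-scaled); we
adopt it so clustering reflects co-expression shape, not expression
magnitude. Cluster indices are relabeled by descending mean log2
fold-change, so cluster 4 is always the VI-down cluster.

**Scoring.** Bulk samples are scored by the mean z-score of a cluster's
genes against reference statistics from a stated cohort — the training
cohort's statistics are reused verbatim when scoring external data.
Spots are scored by the binned-control module score (24 expression
bins, 100 control genes per set gene, seeded sampling; controls drawn
without replacement within a bin when possible). Up-minus-down scores
are plain elementwise differences.

**Spatial statistics.** Spots with fewer than 250 detected genes are
dropped; expression is scaled to 10,000 counts per spot and
log1p-transformed. Spatially weighted local correlation uses a bisquare
kernel by default (a Gaussian kernel is provided for the
large-bandwidth limit, where every local coefficient converges to the
global correlation). The published bandwidth of "five" carries no unit;
we interpret it in spot-pitch units, so bandwidth 5 at a 100 µm pitch
means a 500 µm kernel scale. Region association fits
`score ~ region + (1 | section)` by REML after dropping regions with
fewer than 200 annotated spots and downsampling the rest to 200 spots
each (seeded); contrasts are Wald tests against the normal-lung
reference with Bonferroni adjustment. The high-grade VI contrast
restricts to high-grade-pattern spots and tests the tumor-level VI term
by likelihood ratio with the pattern kept as a fixed effect. The
protocol's description of this model family is internally inconsistent
(binomial in one place, linear in another); scores are continuous, so a
Gaussian linear mixed model is the coherent reading and is what we fit.
Proximal/distal binning measures the Euclidean distance to the nearest
spot *center* carrying the focus annotation — spot centers are the only
geometry in the data model — with proximal defined as ≤ 1 mm
(annotated spots are at distance 0), and a section without any focus
counted entirely proximal.

**The VI predictor.** Candidate genes are the FDR < 0.01 set; the
48-gene panel takes from each cluster a quota proportional to the
cluster's share of significant genes. Two details the protocol does not
state had to be fixed: quotas are integerized by largest remainder
(ties broken toward the larger cluster), and within a cluster genes are
taken in ascending p-value order (ties by |log2FC|, then identifier).
The classifier is a binomial-logit ridge GLM fitted by IRLS on
standardized features with an unpenalized intercept; the penalty is
chosen from 30 log-spaced values in $[10^{-3}, 10^3]$ to maximize mean
AUROC over 5 stratified inner folds, ties resolved toward the stronger
penalty. Outer evaluation repeats a stratified 70/30 split 100 times,
re-running differential expression, clustering, and feature selection
inside each training split so no test information reaches any training
step; a training split with fewer significant genes than the panel size
falls back to the top genes by p-value (logged), which is what makes
null-calibration runs of the full pipeline possible at all. AUROC is
pairwise concordance with half credit for ties (the normalized
Mann–Whitney U), with a percentile bootstrap CI (2000 replicates) and
a Wilcoxon rank-sum test against AUROC = 0.5.

**Survival and heterogeneity.** Cox proportional-hazards fits (Efron
ties) and Kaplan–Meier/log-rank comparisons are delegated to the
survival package, with the package's own tests pinning them to a
brute-force partial-likelihood maximization and a hand-computed
observed-minus-expected statistic. Predictor-score hazard ratios are
reported per SD of score, since the original per-unit scale is not
stated. Multi-region analysis downsamples every tumor to two regions,
contrasts intra-tumor with inter-tumor absolute score differences
(two-sided Wilcoxon; the inter draw count defaults to the number of
tumors so the two sets are the same size), reports the Spearman
correlation of paired-region scores with randomized A/B assignment, and
ranks genes by region–region Spearman correlation for a preranked
enrichment test of the predictor panel.

**Enrichment.** Preranked GSEA uses the classic weighted
Kolmogorov–Smirnov running sum (weight exponent 1 — the protocol does
not state its exponent) with seeded gene-label permutations; the
p-value is one-sided toward the observed sign, normalized over
same-sign permutations, with a +1 pseudo-count. Phenotype permutation
is impossible in preranked mode, which is why gene-label permutation is
the scheme. Over-representation uses the one-sided hypergeometric tail.

## The synthetic-data generator

`sim_design()` fixes the study conditions. Defaults: 2000 genes, four
planted modules of 115/37/182/140 genes (the derived signature's
cluster sizes; scaled proportionally if the simulated transcriptome is
smaller), log2 effects +1/+1/+1/−1 in VI vs LMP, NST expressing 40% of
the VI effect (the protocol treats NST as intermediate but does not
quantify it — this is a free parameter, not an estimate), grade
probabilities 0.22/0.54/0.24, log-normal library sizes around 2
million, log-normal gene dispersions (meanlog log 0.1, sdlog 0.5 — a
realistic biological-variation spread), and an additive two-site batch
shift (SD 0.1 on the log mean, location only).

One term goes beyond the minimal data model: a per-sample, per-module
latent activity (`module_sd = 0.35`). Without it, the three up-modules
are statistically identical and *no* method could recover them as
distinct co-expression clusters, so cluster-recovery tests would be
vacuous. With it, each module has its own correlation structure, which
is also how real co-expression modules behave.

Two calibration checks deliberately switch this latent off
(`module_sd = 0`, zero effects), because each needs the data the
statistical guarantee speaks about: (i) false-discovery control of
permuted-label differential expression is a statement about independent
genes, and label permutation is only a true null when no effect is
planted — with planted effects, chance imbalance of the permuted groups
leaks real signal; (ii) null nested-CV AUROC sits at chance only
without a shared latent factor: resampling train/test splits from one
finite cohort under a latent factor couples the splits (a training
split that chance-aligns with the latent forces the complementary test
split the other way), biasing null AUROC *below* 0.5. Both effects are
properties of the data, not of the pipeline, and both are measured in
the decision record of this package's development. What the passing
tests consequently do **not** show is FDR control under arbitrary
inter-gene correlation — no BH-based pipeline offers that guarantee.

Spot grids are square lattices (hexagonal geometry adds nothing to the
statistics being exercised) at 100 µm pitch with painted rectangles and
discs (normal lung, stroma, desmoplastic stroma, lepidic, solid, VI
focus); later paints win with a warning. Each label has a fixed
module-activity profile, the VI focus carrying the strongest module-1/3
elevation and module-4 suppression, and VI-positive sections add a
bonus elevation in high-grade regions so tumor-wide angioinvasive
expression exists away from the focus. Multi-region tumors draw a
standard-normal tumor latent and add region noise (SD 0.25); survival
times are exponential with hazard $\lambda_0 e^{\beta s}$ and uniform
censoring calibrated to a target censor fraction. What the generator
does *not* emulate: realistic transcriptome-wide covariance beyond the
planted modules, mean–dispersion trends, zero inflation, or histology
images — so passing tests demonstrate correctness of the machinery on
its stated model, not clinical performance.

## Problem sizes and determinism

Every stochastic step takes an explicit seed, split into per-stage
substreams (`stage_seed()`), so any stage reproduces in isolation and
equal seeds give identical tables. The test suite runs cohorts of
60–200 samples with 120–2000 genes, 20 outer CV iterations for null
calibration and 2 for recovery, 60 permutation replicates for the FDR
check (the per-replicate false-discovery proportion is binary, so
precision comes from replicates), and 400–1600-spot grids; the
acceptance script uses the discovery-scale cohort (103 samples, 2000
genes), a 60-sample validation cohort, 63 two-region tumors, and three
400-spot sections. These sizes were chosen so a complete run is a
desk-scale computation on one CPU.

## Known limitations

- The likelihood-ratio test uses plug-in dispersions; with very few
  samples its extreme tail is mildly liberal (quasi-likelihood F-tests,
  which would absorb this, are out of scope).
- Reference-batch harmonization models location and scale only; it
  cannot remove batch effects that change gene–gene correlation.
- The module score depends on the control-gene draw; with the default
  100 controls per gene the seed-to-seed spread is well under a tenth
  of the score SD, but tiny gene universes make it coarser.
- `region_association` requires at least two sections for the random
  intercept and falls back to a fixed-effects model (with a warning)
  for a single section.
- GSEA p-values are permutation-based with a +1 pseudo-count and
  cannot go below `1/(nperm + 1)`.
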