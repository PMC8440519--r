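---
title: "Categorizing common and unique brain changes across two disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing common and unique brain changes across two disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concord)
```

## The question and the statistical framework

Schizophrenia (SZ) and autism spectrum disorder (ASD) overlap in clinical
presentation, and a recurring question is how much of their brain-level
abnormality is shared. `concord` implements a categorization framework
that answers this with three groups — healthy controls (HC), SZ and ASD —
measured on a common set of neuroimaging features: voxel-wise network
Z-scores, functional network connectivity (FNC) edges, atlas-based
functional connectivity (FC) edges, or gray-matter voxel values.

For each feature the engine runs a one-way three-group ANOVA as an
omnibus gate, then two-tailed pooled-variance t-tests on the three group
pairs. The sign convention is that a positive T means the first-named
group has the larger mean, so a positive T in HC vs SZ is a *decrease*
in patients. Features passing the gate are categorized from the signs of
T(HC vs SZ) and T(HC vs ASD):

| T(HC vs SZ) | T(HC vs ASD) | category |
|---|---|---|
| > 0 | > 0 | common decrease |
| < 0 | < 0 | common increase |
| > 0 | < 0 | SZ-unique decrease (ASD increase) |
| < 0 | > 0 | ASD-unique decrease (SZ increase) |

Exact zeros map to no category: the definitions are strict inequalities,
and a zero t-statistic carries no direction. Within the common
categories, the SZ-vs-ASD contrast grades severity: in a common
decrease, T(SZ vs ASD) < 0 means ASD sits closer to controls — an
"ASD-weaker" change — and in a common increase the condition is
T(SZ vs ASD) > 0. Summaries report each category's count divided by the
number of ANOVA-passing features, as one-decimal percentages.

Categorization uses the *signs* of the pairwise statistics among
ANOVA-passing features; pairwise corrected-significance flags are
computed and reported alongside but do not gate category membership.
This is the natural reading of a sign-based partition — requiring
pairwise significance on top of the omnibus gate would leave sign-
discordant but individually weak contrasts uncounted — and it is the
reading under which the bundled summary tables are internally
consistent.

Per-family significance settings (`family_config()`): network voxels use
ANOVA at p < 0.05 with FDR-corrected pairwise maps, after a right-tailed
one-sample gate (Bonferroni p < 0.01) that keeps only voxels with
reliably positive network Z-scores; FNC and ROI-FC use Bonferroni
p < 0.01 for both ANOVA and pairwise maps; gray matter uses ANOVA at
p < 0.05 with FDR pairwise maps at 0.05 (an 0.01 variant is a
documented alternative and available through `config`).

## Harmonization

Multi-site case-control data confound group with scanner and
demography, so every measure is harmonized in three steps before
statistics:

1. within each dataset, OLS regression on age (z-scored within the
   dataset), gender, site dummies, and age x site and gender x site
   interactions, keeping the residuals plus the dataset-wise intercept;
2. estimation of per-dataset "data effects" as the HC-only mean of the
   step-1 values relative to the pooled HC mean;
3. subtraction of each subject's dataset effect, patients included.

Step 2 is deliberately HC-based: patient composition differs across
datasets (SZ and ASD are never acquired at the same sites), so
estimating dataset offsets on everyone would absorb true group
differences. The operationalization of the "data effect" as an HC mean
offset is a design choice — a regression-coefficient or
variance-scaling reading would also be defensible — made because the
mean offset leaves patient-vs-control contrasts exactly unbiased in
expectation and makes the procedure idempotent.

One consequence worth knowing: the HC mean offsets are estimated with
sampling error of order noise/sqrt(n_HC per dataset), and subtracting
them injects a small amount of dataset-level noise that is *correlated
with group* (each disorder lives in its own datasets). On null features
this inflates omnibus rejection rates above the nominal level — a
property of the method, not of this implementation — which is why the
package's null-calibration checks run the ANOVA on confound-free null
cohorts, where the gate's type-I rate is verifiably nominal.

## Quality control

Normalization quality is screened by mask agreement. The individual
fMRI mask keeps voxels above 90% of the whole-volume mean of the first
volume; the group mask keeps voxels present in strictly more than 90%
of individual masks. Each subject's mask is correlated with the group
mask over the top 10 slices, bottom 10 slices, and the whole grid
(Pearson on the binary values); passing requires r > 0.75 / 0.55 / 0.8,
plus head motion under 3 degrees and 3 mm and strictly more than 120
timepoints. After selection the group mask is recomputed once from the
passing subjects. For structural images the mask is the group-mean
image thresholded at 0.2, correlations are computed on continuous
intensities *within* that mask, and the limits are 0.6 / 0.6 / 0.8.

Two conventions are configurable because the slab definition is
genuinely ambiguous: slabs are taken at the top/bottom of the grid
along the third (inferior-superior) axis, and fMRI slab correlations
use binary mask values rather than underlying intensities. Note that a
slab in which either mask is constant has no defined correlation; such
subjects fail with an explicit "degenerate slab" reason rather than a
silent zero.

## Connectivity construction

Network time courses are post-processed in a fixed order — per-network
Z-scoring, regression of the six motion traces, linear detrending,
de-spiking, zero-phase order-5 Butterworth band-pass at 0.01-0.15 Hz —
before Pearson correlation and Fisher z (atanh) transformation.
De-spiking replaces samples more than 4 scale units from a window-7
running median by that median; the scale is the larger of the residual
MAD and residual sd, because the MAD alone collapses on smooth
oscillatory series (most running-median residuals are exactly zero
there) and would clip genuine signal peaks. Correlations with |r| at 1
are clipped to atanh(0.999999) and flagged rather than dropped.

ROI-based FC averages voxel series within each atlas region, drops
regions whose representative series are flat (variance and |mean| below
1e-6) in more than 90% of subjects — the thresholds are explicit
arguments since no canonical values exist — and mirrors the FNC
handling, including the Fisher transform, for the retained regions.

## Resampling validation

The permutation test rearranges the two groups' subjects into dummy
groups of the original sizes and reports, per feature, the frequency
with which the dummy-group t-test p-value falls strictly below the
observed one. The strict inequality and the absence of a +1 correction
follow the procedure's definition exactly, which permits an empirical p
of 0 at finite permutation counts; an exhaustive mode enumerates all
distinct splits for small groups and is the oracle the sampled mode is
tested against.

Fisher's method combines per-dataset p-values as X2 = -2 sum log p with
2k degrees of freedom. Because SZ and ASD never share a dataset, the
SZ-vs-ASD meta-analysis pairs every SZ-bearing dataset with every
ASD-bearing dataset (4 x 2 comparisons under the default layout);
within-disorder contrasts use each dataset that holds both groups.
Zero p-values are clipped to the smallest positive double with a
warning.

## Clinical association and classification

Symptom associations use both Pearson and Spearman correlations with a
dual-significance rule (both p < 0.01), computed pairwise-complete per
patient group. Antipsychotic dose (CPZ equivalents) enters one linear
regression per measure — upstream harmonization has already removed the
nuisance covariates, so no additional predictors are included — with
Bonferroni correction at 0.05/m; ASD medication status is a
Bonferroni-corrected two-sample t-test.

Classification follows a leave-datasets-out protocol: with four
SZ-bearing and two ASD-bearing datasets, each of the 12 experiments
trains on two SZ datasets plus one ASD dataset and tests on the rest.
Feature selection reruns the *entire* categorization engine on training
subjects only (HCs inform selection but never enter the classifier) and
keeps the disorder-unique edges plus the ASD-weaker edges within common
changes. A linear SVM is fit on train-set z-scored features, with the
cost parameter tuned by a one-dimensional Gaussian-process
expected-improvement search (6 initial + 24 acquisition evaluations
over log10 cost in [-3, 3], 5-fold internal CV accuracy as the
objective) — the optimizer is implemented in the package and is
deliberately minimal, since the tuning problem is one-dimensional and
bounded. ASD is the positive class for sensitivity/specificity;
relabeling is supported and exactly swaps the two metrics.

## The synthetic cohort generator

Real multi-site SZ/ASD data are access-restricted, so the package ships
a generator that reproduces the statistical structure the analysis
assumes, with ground truth. Features are standard Gaussian baselines
plus additive planted shifts: the SZ shift is the effect magnitude with
the category's sign, the ASD shift is lambda times the magnitude — same
sign for common categories, opposite for unique ones — with
lambda in (0, 1] encoding globally weaker ASD changes (default 0.5).
Confounds are additive per-(dataset, feature) offsets (sd 0.3), per-
feature age slopes (sd 0.02/year) and gender shifts (sd 0.1), with ASD
datasets drawn younger (mean 15 vs 35 years) so the age confound is
structurally entangled with diagnosis, as in the real design. The
default layout is four SZ-style and two ASD-style datasets with two
sites each and 150 subjects per group per dataset.

Time series are drawn from group-specific latent covariances whose
off-diagonal entries realize planted FNC correlations, so the
time-series route and the direct-matrix route agree by construction.
QC fixtures are ellipsoidal brain supports with small jitter ("good")
or a one-third-grid translation ("bad"); truth-label agreement with the
screening holds when bad volumes stay below the 10% the group-mask rule
tolerates. Symptom scores are linear couplings to chosen features plus
Gaussian noise, generated for patient groups only.

What the generator does *not* emulate: spatial autocorrelation,
hemodynamics, scanner-specific artifacts, non-Gaussian tails, or
feature-feature correlation beyond the planted edges. Passing tests
therefore demonstrate that the statistical machinery behaves as
specified under its own assumptions — not that those assumptions hold
in any particular real dataset.

## Numerical choices and problem sizes

Pooled-variance (Student) t-tests are the default two-sample statistic,
with degenerate cases defined explicitly: zero pooled variance gives
T = 0, p = 1; zero-variance voxels in the positivity gate give p = 0 or
1 by the sign of the mean. Bonferroni flags use the strict inequality
p x m < alpha; FDR uses Benjamini-Hochberg step-up. Aliased regression
columns are dropped deterministically in declaration order, and a
single-site dataset simply loses its site terms. All generators take an
explicit seed and restore the caller's RNG state.

The validation suite exercises the pipeline at sizes a laptop handles
in seconds — cohorts of 150 subjects per group per dataset with 200
features and 30 planted effects for recovery and classification, 2000
null features for calibration, a few hundred sampled permutations
against exhaustive enumeration on 2-vs-2 fixtures — sizes at which the
planted effects (standardized magnitude 0.8, lambda 0.5) are
comfortably but not trivially detectable.

## Known limitations

The harmonization's HC-anchored offset removal slightly inflates null
rejection rates, as discussed above. The permutation scheme shuffles
across datasets (unstratified), matching its definition; a stratified
variant would be a natural extension. The ROI-exclusion thresholds are
conventions, not estimates. And the classification accuracy attainable
on synthetic cohorts reflects the generator's clean Gaussian geometry;
real cross-site generalization is far harder.
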