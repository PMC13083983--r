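---
title: "Multi-region radiomics signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-region radiomics signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpvpipe)
```

## What the package models

`rpvpipe` implements the full analysis chain used to build composite
radiomics predictive vectors (RPVs) from multi-region chest-CT
segmentations: three regions of interest per scan (the lesion, a
perilesional annulus of 5 mm physical thickness, and a spherical
parenchymal reference patch of 2 cm diameter), a fixed catalogue of 666
quantitative features per region (1,998 per scan), reliability filtering by
intraclass correlation, standardisation and ComBat harmonisation across
acquisition sites, Spearman relevance/redundancy reduction followed by
LASSO logistic regression, and evaluation by ROC analysis, logistic
modelling with a nomogram, and Kaplan-Meier/Cox survival stratification.

Because institutional imaging cohorts cannot ship with a package, every
stage is testable against a synthetic phantom generator whose statistical
structure mirrors what the pipeline assumes: label-dependent lesion
intensity and texture, per-site batch effects, a second rater's
segmentation, test-retest acquisitions and label-linked survival.

## Region geometry

Volumes are resampled to a common grid (the analysis default is
1 x 1 x 2 mm) with trilinear interpolation for images and nearest-neighbour
for masks, which preserves binarity and cannot merge disjoint masks.  The
annulus is obtained by metric dilation: a voxel belongs to the dilated set
exactly when its centre lies within the physical radius of some lesion
voxel, so the shell has the stated physical thickness on anisotropic grids.
The dilation is computed as an exact FFT convolution with the ellipsoidal
structuring element, which is equivalent to thresholding the Euclidean
distance transform while staying exact for the integer counts involved.
The parenchymal patch is a 2 cm metric ball placed uniformly at random
among all feasible centres (fully inside the background, disjoint from
lesion and annulus); real studies place it by radiological judgement, so
the random-but-reproducible rule here is a phantom convention, not a claim
about clinical placement.

Coordinates follow the NIfTI-friendly convention: 0-based voxel indices,
world position `origin + index * spacing`.

## The 666-feature catalogue

The per-ROI catalogue is: 18 image types x (18 first-order + 18 grey-level
co-occurrence features) = 648, plus 14 mask-only shape features and 4
box-counting fractal-dimension features.  The image types are the original
volume, the 8 subbands of a single-level undecimated coiflet-1 wavelet
decomposition (named L/H per axis, e.g. `LLH`), one Laplacian-of-Gaussian
response at sigma = 2 mm, and the 8 wavelet subbands of that LoG response.
The undecimated transform keeps every subband on the acquisition grid, so
ROI masks apply unchanged; the analysis filters are normalised so constants
pass through the low-pass chain unchanged and vanish in every detail
subband.  The catalogue is configurable (bin count, LoG scale) but its
default composition always totals 666 per region.

Numerical conventions worth noting:

* **Discretisation** is fixed-bin-width, anchored at the ROI minimum
  (width = range/32 by default); adding a constant to the image leaves all
  discretised texture features unchanged.
* **GLCM** features use the 13 unique 3D directions at distance one voxel,
  symmetric matrices, averaged over directions.  On a single-grey-level
  region the co-occurrence correlation is undefined; it is fixed at 1 so
  degenerate inputs are deterministic.
* **First-order** variance/SD are population moments; skewness and kurtosis
  of a single-voxel region are reported as explicit missing values.
* **Shape** features are spacing-aware and computed from the mask alone, so
  no intensity filter can alter them.  Axis lengths derive from the PCA of
  the voxel-centre cloud; the maximum 3D diameter uses surface voxels
  (deterministically subsampled above 2,500 points, an error of well under
  a voxel at phantom scale).
* **Fractal dimension** is estimated by box counting: boxes of edge
  `eps` voxels anchored at the object's bounding-box corner, counts
  `N(eps)`, and FD = the negative slope of the least-squares line of
  `log N(eps)` against `log eps` (R-squared reported).  Default box edges
  are powers of two up to a quarter of the smallest bounding-box axis.
  Whether such an FD should be computed on the binary mask or on
  thresholded intensities is genuinely open in the field; the catalogue
  includes both (mask FD plus threshold FD at the 25/50/75% intensity
  quantiles).

## Reliability filtering

Feature reproducibility uses ICC(2,1) - two-way random effects, single
measures, absolute agreement - computed from the ANOVA mean squares of the
subjects-by-raters matrix.  The absolute-agreement form was chosen as the
conservative standard for two-rater radiomics reliability: a constant
offset between raters lowers it, which a consistency ICC would forgive.
Inter-observer filtering defaults to ICC >= 0.8 and test-retest filtering
to ICC >= 0.9, both computed on raw (pre-harmonisation) features; the
pipeline manifest records the counts surviving each step.

## Standardisation and ComBat

Features are standardised to zero mean and unit population SD; the fitted
means/SDs are frozen and re-applied to held-out data.  Batch effects are
then removed with the parametric empirical-Bayes location/scale model:
per-feature data are centred by the batch-size-weighted grand mean and
scaled by the pooled within-batch variance; per-batch location and scale
effects are shrunk toward normal and inverse-gamma priors by the standard
iterative conditional scheme (convergence tolerance 1e-4; failure raises an
error rather than truncating).  Two deliberate differences from the
single-shot reference routine: the model is a frozen object that can be
applied to new cases from known batches (no reference-free extrapolation to
unseen scanners), and a fit-time recentring constant per feature makes the
adjusted training data preserve the grand mean exactly.  Batch variances
use population denominators, which makes the single-batch case an exact
identity map.  Labels are withheld from harmonisation by default to avoid
leaking outcome information through the batch model; with labels balanced
across batches a planted class effect passes through within a few percent.

## Signature construction

"Spearman" dimensionality reduction is interpreted as relevance ranking by
|Spearman rho(feature, label)| with greedy redundancy elimination: walking
down the ranking, a feature is kept only if its |rho| with every kept
feature is at most 0.9, stopping at 50 survivors.  Both thresholds are
arguments.  The signature itself is L1-penalised logistic regression with
the penalty chosen by 10-fold cross-validated deviance on stratified folds
fixed by the seed; non-zero coefficients define the RPV, and the default
decision threshold is the Youden-optimal cutoff on the training ROC, the
standard rule when a single reported cutoff is required.  A benchmark
utility evaluates selector x learner grids (elastic net, plain GLM, random
forest, SVM, a majority-class dummy as the chance control) on one shared
set of stratified folds, with ties broken toward fewer selected features.
Hyper-parameter grids for the non-winning learners are pragmatic defaults,
not tuned.

All data-dependent steps - standardisation, ComBat, ICC filtering, the
Spearman filter, the penalty search - are fitted strictly inside the
training partition; `rpv_predict()` replays the frozen transforms.

## Evaluation

ROC curves are empirical step functions with mid-rank tie handling, AUC by
the trapezoidal rule (identical to the Mann-Whitney concordance
probability), and percentile-bootstrap 95% confidence intervals (2,000
replicates by default) for AUC and accuracy; the bootstrap was chosen
because it is agnostic to the metric.  Cohort comparisons follow the
two-sided Pearson chi-square without continuity correction for categorical
variables and the Wilcoxon rank-sum test for continuous ones, with one-way
ANOVA exposed as an option because the two conventions coexist in the
field.  The nomogram maps each multivariable-model term to a 0-100 points
scale proportional to `|beta| * (x - x_ref)` and converts total points to
probability through the logistic link on a 1,000-point lookup grid; reading
the nomogram agrees with the model to well under 0.005 in probability.
Survival stratification uses Kaplan-Meier estimates, the log-rank test and
a univariable Cox model (high vs low risk by the Youden-derived training
threshold by default, median split available).  Synthetic survival is
administratively censored at 36 months by default, reflecting a three-year
follow-up clock.

## What the phantom does and does not emulate

Each case is a roughly spherical lesion (radius jittered up to +/-20%)
embedded in a textured background built from a low-frequency sinusoid plus
Gaussian-smoothed noise - the cheapest texture with a controllable
autocorrelation that still produces non-degenerate co-occurrence matrices.
The class label enters twice: as a mean intensity shift of the lesion (half
of it on the annulus, reflecting perilesional invasion) and as a
lengthening of the tissue-texture correlation length, so both first-order
and texture features carry signal, mirroring signatures that mix both
classes.  A per-patient random intensity intercept (SD 8 HU) models
inter-patient heterogeneity and keeps discrimination away from ceiling at
realistic effect sizes.  Site effects are affine intensity maps
(`v -> scale * v + shift`; defaults 0/+25 HU and x1/x1.1 for two sites).
Survival hazards attach to the latent label, not to any fitted score, so
prognostic-stratification tests are well-posed.  The second rater is a
one-voxel morphological perturbation of the lesion mask; the retest scan
redraws acquisition noise only.

The phantom makes no attempt at anatomically realistic lungs, DICOM
acquisition physics, partial-volume effects at the pleura, or
histology-dependent morphology.  Passing tests therefore demonstrate that
the pipeline's statistical machinery behaves as designed under its own
assumptions - not that any particular clinical accuracy would be attained
on real cohorts.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script experiments run at desk scale, chosen
once as the smallest sizes at which each check is statistically meaningful:
phantom grids of 60 x 40 x 20 voxels at 1 x 1 x 2 mm; 200 replicate
draws for the ICC and Cox calibrations; 50 seeds for LASSO selection
consistency and hazard-ratio recovery; two batches of 200 cases for ComBat
recovery; and, for the end-to-end monotonicity experiment, label effects of
0, 10 and 25 HU (null, ~1.2 and ~3 times the inter-patient SD) with 100
training and 60 held-out cases per effect size - the training size keeps
the true signal ahead of the extreme rank statistics of ~2,000 noise
features in the Spearman stage, and the test size keeps the expected AUC
separation between adjacent effect sizes several times the sampling error
of a 60-case AUC.

## Known limitations

* The GLCM family is the only texture matrix family implemented (no
  GLRLM/GLSZM/NGTDM); the catalogue is extensible but its default is fixed
  at 666 per region.
* Non-parametric ComBat priors, covariate-preserving ComBat and
  longitudinal variants are out of scope.
* ICC forms other than (2,1) are not exposed.
* The nomogram handles numeric model-matrix terms; factor covariates enter
  through their dummy columns.
* The phantom's parenchymal patch placement is a synthetic convention (see
  above), and its "no appreciable aerated lung" clinical criterion has no
  analogue here.
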