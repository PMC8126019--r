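---
title: "Radiomic classification of glioblastoma habitats: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic classification of glioblastoma habitats: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Glioblastoma multiforme (GBM) presents on MRI as a heterogeneous lesion with
four clinically meaningful tissue compartments ("habitats"): a necrotic core,
the solid enhancing part, peritumoral tissue, and peritumoral edema.
Delineating these compartments matters for biopsy planning, resection and
radiotherapy. `habitomics` implements a radiomics pipeline that, given
co-registered multiparametric MR volumes (contrast-enhanced T1, T2-weighted,
T2-FLAIR, and ADC maps) and an integer mask labelling the four habitats,

1. extracts a fixed 1316-value feature vector per (subject, habitat) region,
2. compares four classifier families under leave-one-out cross-validation
   (LOOCV) with one-vs-rest metrics and ROC/AUC, and
3. ranks features by random-forest importance and examines the correlation
   structure of the top 20 features against the habitat label.

Because patient data cannot ship with a package, a synthetic phantom
generator produces cohorts with the statistical structure the analysis
assumes; every claim the test suite makes is made on phantoms.

## The feature battery

Each region is processed once per modality; the per-modality block has 329
values and four modalities give 4 x 329 = 1316. The blocks:

* **First-order (16)** - mean, median, min, max, range, variance and standard
  deviation (population convention), skewness and excess kurtosis (defined as
  0 for constant input), energy, entropy and uniformity of the 64-bin
  discretized histogram (entropy in bits; a constant region has entropy 0 and
  uniformity 1), RMS, mean absolute deviation, 10th and 90th percentiles
  (type-7 quantiles).
* **LBP histogram (16)** - the rotation-invariant uniform local binary
  pattern (P = 8 grid neighbours, R = 1, no interpolation of diagonal
  neighbours) is computed for every slice pixel whose full 3 x 3
  neighbourhood lies in the region; codes are pooled over slices and the same
  16 statistics are taken of the pooled code distribution, with entropy and
  uniformity on the natural 10-bin code histogram.
* **Shape (8)** - volume, mesh surface area, surface-to-volume ratio,
  sphericity, spherical disproportion, maximum 3-D diameter, elongation,
  flatness. The mask is shared across modalities; the block is replicated
  under each modality prefix so the battery counts 32 geometry features.
* **GLCM (22) and GLRLM (11)** - see below.
* **SIFT (256)** - descriptor mean and descriptor standard deviation, below.

Intensities are discretized per region with a fixed bin count (default 64)
over the region's observed range; the minimum maps to level 1, the maximum to
level 64, and a constant region maps entirely to level 1. Fixed bin count
rather than fixed bin width keeps the texture matrices comparable across
subjects whose absolute scanner units differ; 64 levels matches the
granularity of the first-order histogram statistics.

### Texture matrices

Clinical MR voxels are strongly anisotropic through-plane, so texture is
computed slice-wise: within each axial slice, symmetric distance-1
co-occurrences are accumulated for the four in-plane directions (0, 45, 90,
135 degrees), pooled over all slices of the region, normalised per direction,
and the 22 co-occurrence statistics are averaged over the four directions.
The direction set is closed under 90-degree rotation, so direction-averaged
features are invariant to in-plane rotation by multiples of 90 degrees (a
tested property). Run-length matrices are accumulated the same way; runs are
broken by the region boundary, and each in-region pixel belongs to exactly
one run per direction, which fixes the mass balance sum(count x length) =
pixel count that the tests assert.

Degenerate conventions are chosen so constant regions stay finite: GLCM
correlation and the first information measure are 0 when their denominators
vanish, and a constant region has contrast 0, energy 1, entropy 0.

### Shape

Surface area uses a marching-tetrahedra triangulation (six tetrahedra per
cube) of the region indicator smoothed with a 1-voxel Gaussian, at iso-level
0.5. Smoothing gives sub-voxel vertex placement, so a digital ball of radius
10 voxels recovers the analytic sphere area to a few percent; meshing the raw
binary indicator would overestimate it badly. Regions too thin to survive
smoothing (e.g. a single voxel) fall back to the raw indicator so every
region yields finite values. Sphericity is clamped to (0, 1] (the mesh can
slightly underestimate area) and spherical disproportion is its reciprocal.
Elongation and flatness are sqrt(lambda2/lambda1) and sqrt(lambda3/lambda1)
of the voxel-centre covariance, with a uniform within-voxel variance of
spacing^2/12 added to each axis so that single-file regions (a 1 x 1 x N
rod) get a small positive elongation instead of 0/0; a single voxel is
isotropic (elongation = flatness = 1). The maximum 3-D diameter is the exact
maximum pairwise distance over boundary voxel centres, computed after an
exact convex-hull pre-filter (per grid line, only the two extreme voxels can
realise the diameter).

### SIFT

No R package on CRAN/Bioconductor provides SIFT, so the package carries its
own 2-D implementation: a difference-of-Gaussian pyramid (sigma0 = 1.6,
three scales per octave, up to three octaves), 26-neighbour extremum
detection with contrast (0.03 on the normalised image) and edge-response
(Hessian ratio r = 10) rejection, one dominant gradient orientation from a
36-bin weighted histogram, and the standard 4 x 4-cell x 8-orientation-bin
descriptor (128 values, L2-normalised, clipped at 0.2, renormalised).
Simplifications, chosen for robustness on small ROI patches: no sub-pixel
keypoint refinement, a single orientation per keypoint, nearest-bin
descriptor accumulation, and at most 40 keypoints (by DoG response) per
slice. Descriptors are pooled over a region's slices and summarised by their
element-wise mean and *population* standard deviation (so duplicating slices
leaves the summary unchanged, a tested invariant) - 256 deterministic values.
A learned bag-of-words codebook was deliberately avoided: it would have to be
fitted inside every cross-validation fold to avoid leakage, whereas the
mean/SD summary is a fixed function of the region. A flat region with no
keypoints yields 256 zeros with a warning; small necrotic cores do this
routinely and it is informative rather than harmful (the zeros themselves
separate small from large regions).

## The phantom generator

Each subject is four nested ellipsoidal shells (necrosis innermost, then
solid, peritumoral tissue, edema) in a dim background, rasterised on a
64 x 64 x 32 grid at 1 mm isotropic spacing (unit spacing keeps shape
features hand-checkable). Geometry is jittered per subject (uniform +/-10%
on semi-axes, +/-2 voxels on the centre) so shape features vary across the
cohort; without jitter, LOOCV on shape would be degenerate. Each region x
modality has a profile (mean, noise SD, texture correlation length,
histogram skew). Texture is Gaussian-smoothed white noise with a
region-specific kernel width - a simple, controllable autocorrelation that
gives GLCM/GLRLM/LBP features real signal; skew is introduced by a
standardised lognormal marginal transform that preserves mean and variance.
Default means follow the qualitative contrast logic of GBM MRI, with ADC
inverted relative to T1-CE (necrosis brightest on ADC) so modality blocks
are not redundant. Published descriptions of habitat appearance on MRI are
qualitative, so the numeric profiles are the package's own choice of a
plausible operating point, fixed once.

The `separation` dial in [0, 1] scales all inter-region profile differences:
profiles are interpolated toward their across-region mean, so at
`separation = 0` all four regions have identical intensity statistics.
Geometry cannot be made identical - the shells nest by construction, and
shape features would always identify nested shells - so at reduced
separation the *assignment* of the four labels to the four shells is
additionally randomised per subject with probability `1 - separation`. At
`separation = 0` the label is therefore independent of every feature
(intensity and shape alike) and classification accuracy must sit at chance;
at `separation = 1` the anatomical nesting always holds. This is the
package's resolution of the requirement that the zero-separation phantom be
fully uninformative.

What the phantom does **not** emulate: MR physics (bias fields, partial
volume, Rician noise), registration error, non-ellipsoidal anatomy, and
inter-feature correlation structure of real tumors. Passing the recovery
tests therefore shows the pipeline can detect the kinds of structure it
claims to measure - not that patient-data accuracies are reproduced.

## Classification

The sample unit is one (subject, region) ROI, matching the 4-class habitat
label; region-level metrics are what the analysis reports. An optional
per-slice mode is supported through `majority_vote()`: a region's slices can
be classified individually and rolled up with the documented 50% threshold
(when no label exceeds half the votes, the highest mean class probability
wins).

Under LOOCV, each of the n ROIs is held out once; features are standardized
*within each fold* using training rows only (a leakage test corrupts the
held-out row and asserts the fold's training statistics are unchanged).
Four families are compared:

* **k-nearest neighbours** - hand-implemented on the distance matrix because
  the grid covers euclidean, manhattan and minkowski (p = 3) metrics and the
  ROC analysis needs full class-probability vectors (vote fractions);
  neighbour ties are broken by training index for determinism.
* **Gaussian naive Bayes** (`e1071`), with a floor on within-class SDs so
  constant-within-class features cannot produce degenerate densities.
* **Random forest** (`ranger`), the headline model: 500 trees, 8 candidate
  features per split, unlimited depth by default, probability forests.
* **MLP** - two hidden layers (128/64), ReLU, softmax, full-batch Adam,
  early stopping on the training-loss plateau; hand-implemented since no
  installed package offers a two-hidden-layer perceptron, and seeded weight
  initialisation keeps it reproducible.

`grid_search()` evaluates an exhaustive grid by LOOCV overall accuracy with
first-point tie-breaking; the conventional grids are k = 1..30 with three
metrics for kNN and candidate-features-per-split 100..2000 (step 100, capped
at the feature count) with depth 0..110 (step 10) for the forest.

Metrics follow the one-vs-rest dissection: per class, recall = TP/(TP+FN),
precision = TP/(TP+FP), F1 = 2PR/(P+R), accuracy = (TP+TN)/total; zero
denominators report 0 with a `degenerate` flag. The overall accuracy is
trace/total of the 4 x 4 confusion matrix. AUC is the Mann-Whitney rank
statistic with midrank ties, checked in the tests against exhaustive
concordant-pair counting and against `pROC`.

A caveat the tests respect: leave-one-out on label-free data is pessimistic
(holding out a sample makes its class the minority in training), so chance
level is only approached from below as n grows; the null checks use cohort
sizes where the bias is small against the binomial width.

## Feature analysis

`rank_importance()` averages impurity importance over 10 independently
seeded 500-tree forests on the standardized table, normalises scores to sum
to 1, and ranks descending with registry-order tie-breaking; the top-20 list
feeds `correlation_matrix()`, which appends the habitat label encoded
ordinally 1-4 in anatomical order (necrosis, solid, peritumoral, edema) and
computes Pearson or Spearman coefficients (zero-variance columns are flagged
and set to 0). The heatmap renderer draws an already-computed matrix and
never recomputes it.

## Problem sizes and numerical choices

The study-scale checks use a 23-subject cohort (92 ROI instances) on the
default 64 x 64 x 32 grid; unit tests use 6-subject cohorts on a
40 x 40 x 24 grid. Entropies are base-2 throughout. Quantiles are type 7.
All generators and fits derive per-item seeds from a single base seed via a
fixed linear-congruential mixing, so every result in the package is a pure
function of that seed; the pipeline writes byte-identical CSV/JSON when
re-run.

## Known limitations

* The registry's exact membership of the 16 first-order and 22 GLCM
  statistics is the package's normative choice of standard sets; other
  radiomics toolkits make slightly different choices (and e.g. IBSI
  aggregation variants differ).
* SIFT on 2-D slices of small regions is keypoint-starved; zero vectors are
  common for necrotic cores.
* The phantom's texture is stationary Gaussian within regions; real tumor
  texture is neither stationary nor Gaussian.
* Accuracies reported on clinical GBM cohorts depend on private patient
  data and are not reproducible targets; the package's recovery claims are
  property-based on phantoms.
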