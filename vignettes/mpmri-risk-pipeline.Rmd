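---
title: "Pre-biopsy risk classification from prostate mpMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-biopsy risk classification from prostate mpMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a prostate biopsy, clinicians can combine the NCCN clinical risk
group with a genomic classifier (Decipher) into a three-tier
clinical-genomic risk group: the NCCN group contributes a value 0-3 (low,
favorable intermediate, unfavorable intermediate, high/very-high), the
Decipher category a value 0-2 (cutoffs 0.45 and 0.60), and their sum forms
a six-tier score reported as three tiers. A lesion is *low risk* when
either (i) NCCN low with Decipher low or intermediate, or (ii) NCCN low or
intermediate with Decipher low; a patient is low risk when all of their
mpMRI lesions are.

This package asks whether that label can be predicted *before* biopsy from
multiparametric MRI (T2-weighted, ADC, high b-value) plus the minimal
clinical information available at the time of the exam (age, PSA density,
DRE, PI-RADS). Five logistic models are compared: clinical only (1),
lesion radiomics (2), lesion + normally-appearing tissue radiomics (3),
and the clinical + radiomics combinations (4, 5). The tumor volume proxy
(`HRS6`, here the supplied lesion-mask volume in cc) is forced into every
radiomics model.

## Pipeline stages

1. **Normalization.** T2-weighted intensities are scanner-arbitrary; they
   are mapped through a monotone interpolating spline anchored at the
   origin and at (measured mean, target) knots for gluteus maximus,
   femoral head and bladder (defaults 100/300/1000). High b-value volumes
   are rescaled so the gluteus-maximus mean hits its target (default 100);
   ADC is already quantitative and passes through. The default spline is a
   monotone piecewise-cubic Hermite interpolant (`splinefun(method =
   "hyman")`), with a piecewise-linear mode for hand-checkable mappings;
   both extrapolate linearly above the largest knot, and negative inputs
   are clamped to the origin anchor since magnitudes below zero are
   physically meaningless. Monotonicity is non-negotiable for an intensity
   map; an unconstrained cubic through four knots can oscillate.

   One subtlety: the map interpolates the *knots* exactly, so the mean of
   a mapped reference region equals its target exactly only when the
   region is homogeneous. For a noisy region the difference is second
   order in the in-mask variance (Jensen gap); the test suite checks the
   exact fixed-point, idempotence and order-preservation properties on
   homogeneous reference tissues and the approximate version (relative
   tolerance 2%) under realistic noise.

2. **Radiomics.** 162 features per ROI over the lesion (L), normally
   appearing peripheral zone (NAPZ) and transition zone (NATZ): 3
   sequences x 6 families x 9 histogram descriptors, named
   `ROI_sequence_family_descriptor` (e.g. `L_adc_ene_90`). The `int`
   family summarizes the in-ROI normalized intensities directly. The five
   Haralick families (contrast, correlation, energy, entropy, homogeneity)
   come from voxel-wise texture maps: a 5x5x5 window centered at each ROI
   voxel is taken from the full image (the ROI's surroundings are
   legitimate context), locally rescaled to 0-255, binned into a 128-level
   3D grey-level co-occurrence matrix over the 13 unique unit-displacement
   directions, symmetrized, normalized, and reduced to the five scalars;
   the per-voxel values over the ROI are then summarized by the same nine
   descriptors. The local (per-window) rescaling makes texture comparable
   between tumor and normal tissue and makes every texture feature
   invariant to global intensity offsets.

   Conventions the source material leaves open, fixed and documented here:
   percentiles interpolate linearly between order statistics (type 7); SD
   uses the sample (n-1) convention; kurtosis is excess kurtosis;
   degenerate (zero-variance) samples report skewness/kurtosis 0; grey
   levels map to bins as `floor(level * nBins / 256)`; window rescaling
   rounds half-away-from-zero; entropy uses the natural log; a GLCM with a
   zero-variance marginal has correlation 0; windows are clipped at image
   boundaries (minimum 27 voxels at a corner). The sliding-window engine
   is compiled code; an R-level reference path
   (`rescaleWindow`/`glcm3d`/`haralickFeatures`) and independent
   brute-force oracles in the tests pin both to the definitions at 1e-10.

3. **Risk labels.** `nccnGroup()` implements a configurable rule table
   (defaults: low = stage <= T2a, grade group 1, PSA < 10; high = stage >=
   T3a, grade group >= 4 or PSA > 20; the intermediate split counts
   intermediate risk factors, requiring a single factor, grade group <= 2
   and < 50% positive cores for favorable, with a missing core percentage
   treated as favorable). `sprattLabels()` adds the group values, flags
   the low-risk cells exactly per the rule above, and maps sums >= 4 to
   the high tier. Because the exact six-to-three-tier table is not fully
   reproduced in the source material, the intermediate/high boundary and a
   "strict" reading of the low-risk rule (favorable intermediate only) are
   configuration switches; defaults follow the verbatim rule.

4. **Models.** Radiomics pools are standardized (stored center/scale,
   median imputation, zero-variance columns dropped with a warning) and
   screened by a two-stage adaptive LASSO: ridge-penalized logistic
   coefficients give per-variable weights `1/|b|^gamma` (gamma 1), then a
   weighted L1 path is tuned by stratified 10-fold cross-validated
   deviance. The penalty is chosen by the one-standard-error rule: on null
   data the minimum-deviance rule frequently drags in around a dozen noise
   variables, which defeats the selection-consistency purpose of the
   adaptive weighting, while the 1-SE rule keeps null selections at or
   near zero without losing genuinely planted signal (both observed in the
   test suite); `lambdaRule = "min"` restores the alternative. Forced
   variables (HRS6 always; the four clinical variables in models 4-5, which
   enter unpenalized) bypass selection. The final fit is an unpenalized
   logistic regression on selected + forced variables, falling back to a
   ridge-stabilized fit (fixed small penalty) under separation.
   Selection runs once on the training data; patient-level models are
   refit on worst-lesion patient rows (the lesion with the highest true
   three-tier score).

5. **Evaluation.** AUC is the Mann-Whitney statistic with ties counted
   1/2 (identical to the trapezoidal ROC area). Curves are compared with
   the paired Venkatraman-Begg permutation test: within-sample ranks, the
   summed absolute difference of classification error counts over all rank
   cut-points, and a null built by exchanging each record's paired ranks
   with probability 1/2 and re-ranking (ties broken at random under the
   seed). Internal validation uses the bootstrap optimism correction: each
   resample refits the model-building procedure, and the mean of
   AUC(resample) - AUC(original) is subtracted from the apparent AUC (the
   reference analysis uses 1000 resamples; the tests use 200).
   DRE-negative-subset cells evaluate the models trained on the full
   cohort, mirroring a subset analysis rather than a re-derivation.

## The phantom cohort generator

Real exam data for this analysis are restricted, so the generator is a
first-class, tested module that reproduces the *statistical structure* the
pipeline assumes, not prostate anatomy:

* schematic geometry — ellipsoidal peripheral/transition zones, reference
  tissues (gluteus maximus, femoral head, bladder) with distinct means,
  ellipsoidal lesions placed in the peripheral zone clear of the NAPZ/NATZ
  sites (masks are validated disjoint and non-empty; impossible geometry
  fails naming the constraint);
* per-exam multiplicative gains on the T2W and BVAL scales (uniform on
  0.7-1.4) that the normalization stage must undo; the phantom's pre-gain
  reference tissues sit exactly at the default normalization targets, so
  configured effect sizes read in normalized units;
* two lesion classes: non-low lesions have lower T2 and ADC, higher
  b-value, larger volume (radius factor 1.25) and shorter-range texture
  (Gaussian correlation length 0.4 vs 1.1 voxels on average);
* class structure in the tabular data: lesion classes are correlated
  within a patient through a latent all-low vs mixed patient type
  (mirroring a cohort assembled from a low-risk surveillance arm and a
  higher-risk treatment arm); DRE positivity is concentrated in non-low
  patients (2% vs 70%, the latter matching the higher-risk arm's 23/32);
  PSA/PSAD and PI-RADS are class-shifted with configurable strength;
  Decipher scores are class-conditional Beta draws (low-class mode below
  0.45, non-low above); grade group, stage, PSA and Decipher are drawn by
  rejection against the actual labeling rule, so the ground-truth class
  always equals the recomputed label.

Two design points deserve emphasis. First, **between-lesion variability**:
each lesion carries a random intensity shift (SD 25/140/15 in t2/adc/b
units) and a jittered texture scale in addition to voxel noise. Without
it, ROI averaging makes any nonzero class shift perfectly separable and
every radiomics model saturates at AUC 1.0; with it, the default effect
sizes (-25/-120/+15, i.e. roughly one between-lesion SD) put the planted
models in the high-0.8s to mid-0.9s — overlapping class distributions
rather than a degenerate phantom. Second, the magnitudes of those defaults
are free parameters of this package: the source material describes the
direction of each class difference but not its size, so the defaults were
chosen once to produce that realistic regime and are not tuned thereafter.

What the phantom does *not* model: anatomy, scanner/vendor heterogeneity,
bias fields, registration error, DCE imaging, or any spatial relationship
between texture and biology. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that its statistics behave as designed
under known signal — not that the models would reach comparable
performance on patients.

## Numerical and design choices

* Tie-breaks: rank ties in the AUC use midranks; rank ties created by the
  Venkatraman-Begg exchange are re-ranked randomly under the seed.
* Degenerate inputs: empty masks, single-class outcomes, all-missing
  columns, non-monotone reference configurations and undersized ROIs
  (fewer than 10 voxels) fail with named errors; zero-variance feature
  columns are dropped with a warning; bootstrap resamples with a single
  class are redrawn and counted.
* Determinism: cohorts are a function of (config, seed); selection folds,
  permutations and bootstraps all take explicit seeds; two identical runs
  produce byte-identical result tables.
* Problem sizes in the tests: cohorts of 73 patients (about 190 lesions,
  matching a ~0.58 low-risk fraction and 1-5 lesions per patient), 5 seeds
  for null behavior, 3 for planted-signal patterns, 500 replicates for the
  permutation-test calibration, 200 bootstrap resamples. These are the
  package's reference experiment sizes; all scale through configuration.

## Known limitations

* The bootstrap optimism correction is honest but not magic: for a
  severely overparameterized model (pure noise, p about n/2) the resample
  model memorizes the ~63% of original records it saw, so
  AUC(original) stays well above chance and the estimated optimism is
  roughly half the true optimism. The corrected AUC then lands near
  0.65-0.8 rather than 0.5. This is a documented property of the ordinary
  optimism bootstrap under near-interpolation; the test suite asserts the
  idealized expectation and the corresponding check is expected to fail,
  deliberately, rather than be weakened.
* The patient-level evaluation follows the worst-lesion-by-truth design,
  which uses the label to pick the lesion; the deployable alternative
  (minimum predicted low-risk probability over lesions) is provided as a
  prediction policy.
* `HRS6` is proxied by the supplied lesion mask volume; the habitat-risk
  scoring algorithm that produces it in the original analysis is out of
  scope.
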