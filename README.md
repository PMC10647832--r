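# mpRadRisk

Pre-biopsy risk classification of prostate lesions from multiparametric
MRI (mpMRI), in R.

After biopsy, a clinical-genomic three-tier risk group can be formed by
summing the NCCN clinical risk value (0–3: low, favorable intermediate,
unfavorable intermediate, high/very-high) with the Decipher genomic
category (0–2 at the 0.45/0.60 cutoffs); a lesion is **low risk** when
(i) NCCN low with Decipher low/intermediate, or (ii) NCCN low-or-
intermediate with Decipher low, and a patient is low risk when all of
their lesions are. `mpRadRisk` implements a pipeline that predicts this
label *before* biopsy from the mpMRI exam alone:

* **Normalization** — T2-weighted intensities mapped through a monotone
  spline anchored at reference tissues (gluteus maximus, femoral head,
  bladder → 100/300/1000); high b-value rescaled by the gluteus-maximus
  mean; ADC used in native units.
* **Radiomics** — the canonical 486-feature set: per ROI (lesion, NAPZ,
  NATZ) and sequence (t2, adc, b), nine histogram descriptors of the
  intensities and of five voxel-wise 3D Haralick texture maps (5×5×5
  sliding window, local 0–255 rescale, 128-bin symmetrized GLCM over 13
  directions), plus the lesion volume `HRS6` (cc), forced into every
  radiomics model.
* **Risk scoring** — NCCN rule table, Decipher categorization, Spratt
  score, three-tier group, lesion and patient low-risk flags.
* **Models 1–5** — logistic regressions for P(low risk): clinical only
  (age, PSAD, DRE 0 vs 1–2, PI-RADS 1–2 vs 3–5); lesion radiomics;
  lesion + NAPZ/NATZ radiomics; and the clinical+radiomics combinations.
  Radiomics pools are standardized and screened by a two-stage adaptive
  LASSO (ridge weights, stratified 10-fold CV, one-SE rule).
* **Evaluation** — ROC/AUC (Mann–Whitney), paired Venkatraman–Begg
  permutation comparison, bootstrap optimism-corrected AUC, and the full
  grid of model × lesion/patient level × all/DRE-negative subset.
* **Synthetic cohorts** — the study data are restricted, so a tested
  phantom generator produces exams, masks, clinical records and Decipher
  scores with the class structure the analysis assumes (non-low lesions:
  lower T2/ADC, higher b-value, larger volume, shorter-range texture;
  DRE positivity concentrated in non-low patients).

## Worked example

```r
library(mpRadRisk)

## a phantom cohort: 40 patients, 1-5 lesions each, default effect sizes
coh  <- generateCohort(cohortConfig(nPatients = 40, seed = 42))
coh
#> MpmriCohort: 40 exam(s), 102 lesion record(s), 61 low-risk / 41 non-low

## normalize + extract the 487-value feature vector per lesion
les   <- cohortLesions(coh)
feats <- extractCohortFeatures(cohortStudies(coh), les)
dim(feats)
#> [1] 102 490       # 3 key columns + HRS6 + 486 radiomic features

## label lesions and patients, assemble the modeling table
md <- assembleModelData(feats, scoreCohort(les))

## clinical model vs lesion-radiomics model
fit1 <- fitRiskModel(md, 1, seed = 1)
fit2 <- fitRiskModel(md, 2, seed = 1)
fit2
#> riskModel 2: 4 variable(s) (forced: HRS6)
#>   HRS6, L_adc_int_10, L_adc_cor_90, L_b_int_90

rocAuc(predictLesion(fit1, md), md$low_risk)$auc
#> [1] 0.8882447
rocAuc(predictLesion(fit2, md), md$low_risk)$auc
#> [1] 0.9448221
```

The AUCs say that on this phantom the four pre-biopsy clinical variables
separate low-risk from non-low lesions well (0.89) and the lesion
radiomics — tumor volume plus selected intensity/texture descriptors
(low ADC, high b-value: the same characteristics a radiologist reads) —
separate them better (0.94). These are apparent (in-sample) AUCs on a
synthetic cohort, not patient results. `runExperiment(md)` evaluates
all five models at lesion and patient level, on all records and on the
DRE-negative subset, with optional optimism correction and
Venkatraman–Begg p-values; `runPipeline()` drives the same stages through
a YAML-configured run folder (NIfTI volumes, CSV tables, JSON model
artifacts).

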