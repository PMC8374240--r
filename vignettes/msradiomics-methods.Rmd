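---
title: "Brain tissue radiomics for MS classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain tissue radiomics for MS classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

msradiomics re-implements, as a fully tested pipeline on synthetic data, a
radiomic analysis that discriminates multiple-sclerosis patients (MSP) from
healthy control subjects (HCS) using first-order and 3D texture features
extracted from three brain regions — whole white matter (WM), normal-appearing
white matter (NAWM) and gray matter (GM) — on one conventional channel (T1w,
arbitrary units) and four quantitative MRI maps (PD, MT, R1, R2\*, physical
units). The scientific question behind the design is whether quantitative maps,
whose voxel values are tissue properties rather than scanner-dependent
intensities, carry diagnostic texture information in tissue that *looks* normal
(NAWM, GM), while conventional T1w mostly sees the focal WM lesions.

The stages are: cohort synthesis, preprocessing, fixed-bin-number feature
extraction, univariate screening, balanced-bootstrap stability feature
selection with random-forest recursive feature elimination (RF-RFE), LR/SVM/RF
model evaluation on balanced bootstrap cohorts with DeLong AUC comparison, a
permutation-test overfitting audit, an external-validation harness with frozen
coefficients, and voxelwise feature saliency maps.

## The synthetic cohort generator

No real MRI data ship with the package; `generate_cohort()` produces seeded
phantoms that emulate the *statistical* structure the analysis assumes, not
anatomy:

* **Geometry.** Nested ellipsoids: background → thin CSF shell → GM shell → WM
  core (normalized ellipsoid radius thresholds 1 / 0.88 / 0.62, semi-axes
  0.42/0.38/0.40 of the grid extent). Tissue probability maps are smoothed
  indicator functions (Gaussian, 0.5 voxel), so the 0.9 probability threshold
  used downstream is exercised on genuinely fractional values.
* **Intensity model.** Per tissue and channel, intensity = tissue mean
  (documented constants on plausible scales: e.g. MT ≈ 2.0 p.u. in WM, R1 ≈
  1.05 1/s in WM) × (1 + 3% between-subject jitter) + a spatially correlated
  Gaussian field (correlation length 3 mm, SD 6% of the WM mean) + i.i.d.
  noise (SD 4% of the WM mean). A multiplicative low-frequency bias field
  (amplitude 0.2, correlation length 40 mm) is applied to T1w only.
* **Lesions.** MSP subjects receive 3–8 spheres (radii 4–6 mm) placed fully
  inside the WM core, kept pairwise separated when space allows (so requested
  lesion counts survive as distinct probability-map components) and allowed to
  become confluent in crowded configurations. Lesion contrast is a
  multiplicative factor on the subject's WM mean: hypo-intense on T1w (0.85)
  and MT (0.70), hyper-intense on PD (1.15), mildly hypo on R1 (0.85) and
  R2\* (0.80) — demyelination lowers the myelin-sensitive parameters.
* **Diffuse effects.** `effect_spec()` plants additive mean shifts and
  correlation-length shifts per (channel, ROI) in patients. The defaults
  emulate diffuse qMRI alterations in NAWM/GM (reduced MT/R1/R2\*, increased
  PD) with no diffuse T1w effect. The distributional form of real diffuse MS
  damage is unknown; this mean-shift + correlation-length parametrization is
  an explicit stand-in, not a biological claim.
* **Null cohorts.** With `null_effect = TRUE` *every* class difference is
  zeroed — mean shifts, texture shifts, lesion contrast and the focal lesions
  themselves — because lesion geometry alone erodes the thresholded WM/NAWM
  masks and would leak class information through texture and topology
  features. A null cohort is therefore fully exchangeable between classes,
  which is what a null calibration check requires.
* **Demographics.** Ages uniform on [25, 65]; genders and scanner labels
  assigned round-robin; scanners have no effect on intensities (site effects
  are out of scope).

What passing tests on these phantoms shows: the pipeline's plumbing, its
statistics and its calibration under a known ground truth. What they do not
show: performance on real brains, where anatomy, partial-volume effects,
segmentation error and site effects all matter.

## Preprocessing

Fixed order: resample → threshold probability maps → bias-correct (T1w) →
normalize (T1w).

* `resample_isotropic()` uses tensor-product cubic splines (exact on
  polynomials up to degree 3; voxels centred at `(i - 0.5) * spacing`).
* `threshold_masks()` includes a voxel in a tissue at probability ≥ 0.9
  (boundary inclusive). Voxels supra-threshold in several tissues go to the
  highest probability, ties broken lesion > NAWM > GM > CSF. Composites
  follow the study convention: WM = NAWM ∪ lesion (so WM = NAWM exactly for
  controls) and TIV = CSF ∪ GM ∪ NAWM ∪ lesion. No morphological cleanup is
  applied. An empty NAWM or GM mask is an error, because downstream ROIs are
  undefined.
* `correct_bias()` estimates a smooth multiplicative field in the log domain:
  TIV intensities are clustered into three classes by 1-D k-means
  (deterministic quantile initialization), class log-means are subtracted,
  and a degree-2 polynomial is fit to the residuals over the TIV; clustering
  and fit are iterated three times. A first-pass estimate below 1% means
  "bias-free" and the input is returned unchanged, which makes the operation
  idempotent. Constant or non-positive (already normalized) input passes
  through: a multiplicative bias model only applies to positive magnitude
  data. Genuinely low-frequency intra-tissue fluctuations are mathematically
  indistinguishable from bias and are partially removed with it — the bias
  tests therefore use phantoms with fine-scale texture, where "bias-free" is
  well defined.
* `normalize_tiv()` z-normalizes with mean and *population* SD computed over
  TIV voxels only (population SD makes the "SD = 1" contract exact at any n).
  Only T1w is normalized: the qMRI maps are in standardized physical units,
  and rescaling them would destroy exactly the property the analysis is
  about.

## Feature extraction

93 features per (channel, ROI): 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM,
5 NGTDM, 14 GLDM — `feature_registry()` is the normative list,
reconstructed from the original-image default set of the reference
extraction tool; shape features are deliberately absent. Settings:

* Fixed-bin-number discretization, `N_bins = 50`, level =
  `min(N, floor(N·(x − min)/(max − min)) + 1)`; a constant ROI maps to level 1.
* ROI pre-cropped to its bounding box with 5-voxel padding (clipped at image
  borders) before matrix computation.
* Texture matrices at distance 1 over the 13 unique 3D directions; GLCM and
  GLRLM features averaged over directions (not concatenated); GLSZM zones by
  26-connectivity; NGTDM on 26-neighbourhood means; GLDM with similarity
  tolerance α = 0, dependence defined as 1 + the number of similar
  neighbours.
* Degenerate conventions are explicit because test oracles need them:
  zero-variance GLCM correlation → 1, single-level MCC → 1, 0/0 skewness and
  kurtosis → 0, single-bin entropy → 0 and uniformity → 1, NGTDM coarseness
  cap 1e6, busyness/strength → 0 on vanishing denominators. Idmn/Idn
  normalize by the discretization depth `N_bins`.
* The matrix builders are compiled (Rcpp); every family is verified in the
  test suite against independent brute-force enumeration (all voxel pairs,
  line-walk run enumeration, graph-component zones, per-voxel neighbourhood
  loops) on random grids, plus mass-conservation identities.

Texture features depend only on the discretized levels, so any affine
intensity transform leaves them unchanged (tested); features are translation
invariant inside a larger grid (tested).

## Screening, selection, modelling

* `univariate_screen()`: two-sided Mann–Whitney per feature with Bonferroni
  correction over all features tested in the table (corrected p = min(1,
  m·p)); point-biserial correlation with outcome (t-approximation for its p;
  flagged at |r| ≥ 0.85 and p ≤ 0.05); Spearman correlations with age and
  the feature's own ROI volume (flagged above 0.85); univariate AUC folded
  to ≥ 0.5, computed through the exact U identity AUC = U/(n₁n₂). The
  Mann-Whitney p is exact when n₁n₂ ≤ 400 and tie-free, otherwise the
  normal approximation with tie correction.
* `stability_select()` runs the selection pipeline 100 times on balanced
  bootstrap cohorts of 100 (50 per class, drawn with replacement from the
  training slice only): low-variance filter (drop iff distinct-value share
  < 10% AND top-frequency ratio > 95/5; "ratio of most frequent values" is
  read as the standard top-1/top-2 near-zero-variance criterion) →
  iterative Spearman de-correlation (from each pair with |r_S| > 0.85 drop
  the member with the larger mean absolute correlation to everything still
  kept; ties drop the lexicographically later name) → RF-RFE (100 trees,
  `floor(sqrt(p))` split candidates, one feature dropped per step — maximal
  fidelity to "recursive elimination" at desk scale). Features are ranked
  by selection frequency; ties break by better mean RFE rank, then name —
  the original analysis states no tie rule, and determinism requires one.
* Signature size: `n_features_rule(n) = max(1, round(n/10))` on the
  minor-class size of the training subset. The rule-of-thumb this encodes
  ("about a tenth of the minority class") is ambiguous between truncation
  and rounding, but its reference worked value fixes three features for 28
  minority samples, which `int(28/10) = 2` contradicts and `round(2.8) = 3`
  matches; rounding with a floor of one is therefore implemented.
* Models (`train_model()`): hyperparameters are fixed, never tuned. LR = L2
  logistic regression with C = 1 (ridge `glmnet` at λ = 1/(nC), the same
  objective); SVM = RBF kernel, C = 1, γ = 1/(p·Var(X)); RF = 100 trees,
  `floor(sqrt(p))` split candidates. SVM/LR inputs are standardized with
  training statistics frozen into the model; RF uses raw features. Scores:
  LR predicted probability, SVM decision value oriented so larger = MSP,
  RF vote fraction. Positive class is MSP throughout; sensitivity is MSP
  recall.
* `evaluate_bootstrap()`: 100 balanced test cohorts of 100 (50 per class,
  with replacement from the held-out test slice); median and empirical
  5th–95th percentiles ("90% CI" without a stated method is implemented as
  empirical percentiles). Subject-id disjointness between training and
  evaluation is asserted whenever ids are available.
* `delong_compare()`: paired DeLong test on the raw test-subset scores (not
  on bootstrap cohorts, which would violate independence), Bonferroni over
  model pairs, significance at corrected p ≤ 0.01. The implementation is
  native (structural components); the test suite cross-checks it against an
  independent reference implementation and against a paired-bootstrap
  variance oracle.
* `select_model_type()`: per combination, drop types with median AUC below
  0.7; among survivors the highest median AUC earns a win; most wins
  overall is chosen, ties going to the simpler model (LR over SVM over RF).
* `permutation_audit()`: labels are shuffled within the training and test
  slices separately (class counts preserved), the unmodified pipeline is
  rerun (selection included), and the original vs permuted bootstrap AUC
  distributions are compared with a one-sided Mann–Whitney test at p ≤
  0.01. The default is the audit's single shuffle; `n_permutations` pools
  several shuffles, which is standard permutation-test practice and is used
  by the package's own calibration checks because a single permuted median
  on an 8-subject test slice has a sampling SD of roughly 0.2.
* `external_validate()` applies a frozen model (coefficients and
  standardization constants) to an external table without refitting, with
  the same balanced bootstrap reporting; per-source accuracies are reported
  because an all-negative source's accuracy is the specificity and an
  all-positive source's the sensitivity.
* The pooled-qMRI combination ("qMRIcomb") reruns selection on the pooled
  PD + MT + R1 + R2\* feature table for the ROI, reading "combination of
  features from PD + MT + R1 + R2\*" as a pooled candidate set rather than
  a union of per-channel signatures.

## Saliency maps

`saliency_map()` evaluates one registry feature on the 3×3×3 neighbourhood
of every ROI voxel (truncated at borders; patches with fewer than 2 in-ROI
voxels get 0), then min–max normalizes over the ROI. Patches are discretized
with the *global* ROI bin edges: per-patch edges would make neighbouring
values incomparable. Whether the original analysis used raw or discretized
patches is unstated; this choice is documented here. The first-order mean
map equals a 26-neighbourhood mean filter, which the tests verify by direct
convolution.

## The study driver

`run_study()` wires the stages together from one `study_config()` (YAML
supported): generation, preprocessing, extraction, screening, the stratified
80/20 split (outcome × scanner strata, largest-remainder allocation, with
age/gender balance p-values logged), the full combination grid (each channel
plus qMRIcomb when at least two quantitative channels are present, × 3
ROIs, × 3 model types), DeLong comparisons, model-type choice, a permutation
audit on the best combination, external validation of the T1w models with
frozen coefficients on the validation cohort, and a saliency map for the top
signature feature. Every random draw derives from `global_seed` through
stage-name-hashed offsets, so inserting a stage never shifts another
stage's stream; wall-clock timings go to the plain-text log only, so two
runs of the same config produce bitwise-identical manifests.

## Problem sizes used in the checks

The package's own calibration checks run on desk-scale phantoms chosen to
make the statistics meaningful at interactive cost: feature-count checks on
a 64³ phantom; oracle equivalence on 5×5×5 grids with 4 levels; parameter
recovery and the permutation audit on 40-subject, 48³, MT-only cohorts with
the full 100-iteration selection and 100-cohort bootstraps; the planted
effect there is an MT:WM shift of −0.25 (≈4 pooled SD of the per-subject WM
mean under the default noise model) — the strong-effect regime corresponding
to the headline whole-WM case; null calibration uses 9–10 independent
null-effect cohorts; the end-to-end determinism check uses a 16-subject,
32³, five-channel study with a 5-iteration selection (iteration count does
not affect determinism).

## Known limitations

* The phantoms have no anatomy, no partial-volume mixing, no site effects
  and no MRI physics; conclusions transfer to the pipeline's correctness,
  not to clinical performance.
* The 93-name registry is reconstructed from the reference tool's family
  list and default settings; the original supplementary list was not
  available.
* Bias correction removes the low-frequency component of intra-tissue
  texture along with the bias — an identifiability limit shared by any
  bias-field estimator.
* With very small test slices (the 20% of a 40-subject cohort), per-split
  AUC estimates carry subject-sampling noise that dominates bootstrap CIs;
  calibration statements are therefore made across seeds, not per seed.
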