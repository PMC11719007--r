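---
title: "Peritumoral CT radiomics risk modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral CT radiomics risk modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(perirad)
```

## The problem and the modelling idea

In advanced NSCLC with high PD-L1 expression, upfront single-agent
pembrolizumab is standard, yet roughly half of patients do not respond.
Identifying likely non-responders before treatment would redirect them to
alternative first-line regimens. The hypothesis behind this pipeline is
that the **peritumoral ring** — a ~6 mm annulus of lung parenchyma around
the lesion — carries imaging correlates of the immune microenvironment that
discriminate progressive disease (PD) from disease control (DC), beyond
what intratumoral texture and clinical covariates provide.

`perirad` turns that analysis into a reusable pipeline with a fixed
train/apply asymmetry: everything adaptive (scaling, filtering, feature
selection, hyperparameters, operating thresholds) is learned on the
discovery split alone and then frozen; a runtime guard refuses externally
tagged rows at every fitting stage.

## Stage by stage

### Imaging

CT volumes are windowed and normalized: `x' = clip((HU − (C − W/2))/W, 0, 1)`
with the soft-tissue window C = 40 HU, W = 400 HU as default, since lesions
are annotated under soft-tissue windows. Lesion cores are segmented from a
radiologist-style seed point by Otsu thresholding **inside a local ROI box**
(half-width ≈ 0.75 × lesion diameter): whole-slice Otsu would be dominated
by air and bone. The supra-threshold 8-connected component containing the
seed is kept and holes are filled. Degenerate (near-constant) ROIs and
seeds falling below the threshold raise typed errors rather than returning
empty masks.

Mask geometry is built by Euclidean distance-transform thresholding, which
is mathematically the disk-structuring-element dilation but — unlike
chained discrete brushes — satisfies the exact area identity
`|core_plus_edge| + |ring| = |dilate(core, edge + ring)|`. Defaults: edge
width 2 px (partial-volume boundary at typical 0.7–1.0 mm in-plane
spacing); ring width `round(6 mm / spacing)`, i.e. 8 px at 0.75 mm, with
8 px also the fallback when spacing is unknown. An optional lung mask can
clip the ring; whether rings of pleural-based lesions should exclude chest
wall is genuinely undetermined, so the package exposes it as a flag rather
than deciding silently.

Each lesion contributes up to five axial slices: the largest-area
(central) slice plus two cranial and two caudal steps, clipped to the
lesion extent and the volume.

### The feature bank

The original in-house feature calculator is unpublished, so this package
defines an explicit registry of 176 features per region (528 per slice
across Core / Core-Plus-Edge / Ring), each with a stated formula
(`feature_registry()`), and pins the named headline features to canonical
definitions:

* `OD-CentroidDifference` — ‖intensity-weighted centroid − geometric
  centroid‖ / equivalent radius;
* `RadCentre` — intensity-weighted mean of normalized radial position
  r/r<sub>max</sub> (0 = mass at centre, 1 = at the rim);
* radial-signature statistics (`MeanRadius`, `RadVarianceAngle`,
  `RadSD-Angle`, `RadKurtosis-Angle`) — moments of the boundary distance
  r(θ) ray-marched at 360 equal angles from the geometric centroid, taking
  the outermost crossing;
* `ODEccentricity` / `MinAxis` — eccentricity of the intensity-weighted
  second-moment ellipse and minor axis of the binary-mask ellipse;
* `V-Correlation` — grey-level co-occurrence correlation at offset (1, 0),
  32 levels; `GrayLevel6` — fraction of pixels in bin 6 of a 16-bin
  histogram over [0, 1]; `FFT2` — fractional energy in the second of four
  radial frequency bands of the mask-cropped, zero-padded 2-D FFT.

Quantization grids are fixed at build time (16 histogram levels, 32
co-occurrence levels, both over [0, 1]) so values are comparable across
slices and runs. All features are finite by construction, deterministic,
and exactly invariant to integer translation (verified to 1e−9 in tests);
shape and radial families are invariant to constant intensity shifts while
intensity-weighted families follow them, as documented per feature.
Intensity weighting is linear: whether the original "OD" involved a
log-transform (true optical density) is unknown, and numerical equality
with the original calculator is not claimed — golden tests pin these
definitions against independent brute-force oracles instead.

### Preprocessing

Categoricals are one-hot encoded; unseen levels at apply time map to
all-zero indicators with a warning. Each numeric feature is rescaled by the
discovery-split range to [−1, 1]; external values may fall outside and are
deliberately not clamped. The first-pass filter removes, in order:
near-constant features (variance < 1e−8), weak features (folded univariate
AUC `max(a, 1 − a)` < 0.55), and redundant features (pairwise Spearman
|ρ| > 0.95, dropping the lower-AUC member; ties drop the lexicographically
later name). The original filter's exact thresholds are unavailable; these
defaults implement the same three stated intents, are surfaced in the
configuration, and are echoed in the `filter_report`. Spearman rather than
Pearson because texture features differ by monotone transforms. Clinical
covariates are exempt from filtering by contract.

### Selection and the six-signature menu

Three selectors run with and without the clinical pool, giving six
candidates. SFS greedily maximizes grouped 5-fold CV AUC of a logistic
model, admitting a feature only if it improves the mean CV AUC by more
than 0.03, up to five features (the one-in-five rule for a ~27-patient
minority class). mRMR uses the difference form (relevance MI minus mean
redundancy MI) on 8-bin quantile-discretized features; ReliefF uses all
instances, 10 neighbours and Manhattan distance — all hyperparameters the
source analysis leaves unstated, fixed here as defaults and exposed in
`selection_config()`. Because mRMR and ReliefF only rank, their rankings
are trimmed to model signatures by the same ΔAUC/size rules as SFS, which
reproduces the observed pattern of signatures smaller than five. Ties
everywhere break lexicographically for cross-platform determinism.
Selection is evaluated at slice level with patient-grouped folds — the
model's job is slice-level prediction, and grouping prevents
patient/lesion leakage across folds.

### Model

Outer 5-fold patient-grouped, label-stratified nested CV: an inner grouped
grid search picks the ridge penalty λ ∈ {10⁻², 10⁻¹, 1, 10, 10²} and class
weighting (none / inverse-prevalence) — the only standard logistic knobs
consistent with the overfitting concerns that motivated a linear model —
then the outer-train model scores its held-out fold, giving out-of-fold
slice scores. The final model re-runs the grid search on, and refits to,
all discovery rows. Corrupting a held-out fold's labels provably leaves
that fold's scores unchanged (tested).

The published calculator `eq1_risk()` is kept verbatim behind a mandatory
convention flag. Read literally, the printed formula decreases risk with
the number of metastatic sites, contradicting the reported clinical
direction (PD patients carry more adrenal/liver/bone disease); the
`"conventional"` flag negates the linear predictor before the exponent.
Fidelity first: the default is the literal formula, with a warning when
the caller does not choose explicitly. Its inputs are assumed to be on the
[−1, 1] discovery scale (the original scaling parameters are unpublished),
so the calculator never rescales internally.

### Frequency thresholding and evaluation

A lesion's frequency score is the number of slices with risk score ≥ X; a
lesion is PD if that count ≥ Y; a patient is PD if ≥ Z lesions are PD. All
comparisons are inclusive. The patient-level continuous score for ROC
construction is the **maximum lesion frequency score**, the only statistic
consistent with "any PD lesion makes the patient PD". X is the Youden-J
cutoff of the slice-level ROC on discovery out-of-fold scores; (Y, Z)
maximize the patient-level Youden-J with ties toward smaller values — the
risk-averse direction, since missing a PD patient is clinically costlier
than a false alarm. A lesion with fewer than Y slices can never be PD; the
package warns rather than silently rescaling Y, because the source
procedure does not address this case. AUCs come from the Mann–Whitney
identity with ties counted ½; confidence intervals use the fast DeLong
placement-value estimator (midrank form) with a normal approximation
clipped to [0, 1]; confusion statistics take PD as the positive class.
RECIST labelling uses inclusive boundaries: ≥ +20% of the sum of diameters
is PD, ≤ −30% is PR, disappearance is CR, the remainder SD.

### Survival

Kaplan–Meier curves and the Mantel–Cox log-rank test compare predicted
low- vs high-risk groups for PFS and OS, via thin tidy wrappers around the
`survival` package (events precede censorings at tied times, the standard
KM convention). P-values are reported to machine precision; the source
reports only significance bands, which are one-sided checks against ours.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` plants known structure so the whole chain is testable
without patient data:

* **Cohort**: 97 patients by default at 28% PD prevalence (27/97); ~20% of
  patients carry a second lesion (≈18% multi-lesion rate); five axial
  slices per lesion with radius tapering toward the poles; 96×96 px slices
  at 0.75 mm spacing.
* **Lesions**: soft-edged rotated ellipses (intensity +0.45 over a 0.25
  parenchyma background, ~2 px logistic partial-volume band, Gaussian noise
  SD 0.05) — a minimal model that exercises both shape and intensity
  feature families.
* **Peritumoral signal**: each lesion draws an angular asymmetry amplitude
  and a radial brightening of its ring zone from Gaussians; PD lesions'
  means are shifted by `ring_contrast_effect` standard deviations
  (default 1.5). Both classes vary — the signal is a distributional shift,
  not a deterministic stamp — so slice-level separability is graded
  (≈ Φ(effect/√2)) and the default lands the pipeline's discovery AUC near
  0.85, the reported operating point. The signal lives **only in the
  ring**, making "peritumoral features discriminate" a testable property:
  with effect 0 the end-to-end AUC collapses to chance.
* **Clinical covariates**: class-conditional normals/categoricals in the
  reported directions (PD: fewer pack-years, more metastatic sites,
  slightly younger, worse ECOG).
* **Survival**: exponential event times tied to the TRUE class (never to
  predictions, so the pipeline must earn the separation), with independent
  exponential censoring calibrated to the `censor_rate` in the DC class.
  The default hazard ratio is 8. This is a deliberate compromise: observed
  progression is clustered at the first follow-up CT (~2.5 months), a
  low-variance process that an exponential model cannot express; within
  the exponential family, reproducing the reported log-rank significance
  bands requires a hazard ratio well above the ~4 implied by the median
  ratio alone. The vignette's limitations section returns to this.
* **Determinism**: one integer seed, one `set.seed()`, a fixed draw order;
  identical seeds give byte-identical cohorts.

What the generator does **not** emulate: real anatomy (airways, vessels,
pleura), scanner-specific noise and reconstruction kernels, radiologist
variability in seeds, lesion texture heterogeneity, and non-lung
structures adjacent to the ring. Passing tests therefore demonstrate that
the pipeline recovers planted peritumoral structure under controlled
conditions — not that it would achieve the same accuracy on clinical CT.

## Numerical choices

* Otsu: 256-bin histogram on [0, 1]; between-class-variance ties resolve
  toward the lower threshold.
* Dilation: Euclidean distance transform, threshold `d ≤ w + 1e−9`.
* Radial signature: 360 angles, 0.25 px ray-march step (sub-pixel relative
  to the ≥ 8 px masks enforced by the "mask too small" error).
* Degenerate statistics return 0 (skewness/kurtosis of constant input,
  GLCM correlation with zero variance) so every feature is finite.
* Grid-search ties prefer the larger penalty (more regularization);
  selection ties are lexicographic; Youden ties take the lower cutoff;
  (Y, Z) ties take the smaller counts.
* Fold plans save and restore the RNG state, so seeding is local.

## Problem sizes used by the test suite

Stochastic calibrations run at sizes chosen to keep sampling error well
inside the asserted tolerances while the suite stays quick: the Gaussian
ROC closed form at 1000 per class, DeLong-vs-bootstrap at n = 100 with
2000 bootstrap replicates, log-rank type-I error over 500 null
simulations, and the end-to-end replicate study at 120 patients × 10
seeds with the SFS menu (the full six-signature menu is exercised on a
single run; menu choice changes the winner rarely and the study's
conclusions not at all).

## Known limitations

* Feature values are this package's canonical definitions, not the
  original calculator's; only the names, families and qualitative
  behaviour are anchored.
* The filter thresholds that produced the original "339 of 522 removed"
  are unrecoverable; matching that count is not claimed.
* The exponential survival model caps how cleanly predicted risk groups
  can separate: false-positive DC patients remain in late risk sets, and a
  simulation of the log-rank test at the pipeline's own operating point
  (SN/SP ≈ 0.80–0.85) shows the per-replicate probability of p < 0.01
  saturating around 0.85 even as the hazard ratio grows. Reproducing the
  reported external-set significance (n = 17) under any exponential hazard
  is improbable (~0.2); the observed survival process is simply
  lower-variance than exponential. The replicate study therefore treats
  survival separation as a usually-but-not-always recovered property.
* Slice-level selection with grouped folds is one reading of an
  under-specified procedure; patient-level selection is the plausible
  alternative and would change the cross-validation variance, not the
  interface.
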