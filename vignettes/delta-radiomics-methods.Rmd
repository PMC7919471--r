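---
title: "Methods: intrinsic-variability-normalized delta radiomics for gated PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic-variability-normalized delta radiomics for gated PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the tunable parameters and their
defaults, the numerical choices, and the limits of what the test suite
establishes. It states no empirical result that the tests or the
acceptance script do not themselves compute.

## 1. The statistic and its assumptions

For each image feature (IF) and patient, the package computes

$$\delta_{IF} = \frac{\Delta r_{IF}}{\sigma_{IF}}, \qquad
\Delta r_{IF} = 100\,\frac{IF_{post} - IF_{pre}}{|IF_{pre}|}, \qquad
\sigma_{IF} = 100\,\frac{\mathrm{SD}_k\, IF^{(k)}}{|\overline{IF^{(k)}}|},$$

where $IF_{pre}$ and $IF_{post}$ are the feature values on the static 3D
scans before and during/after treatment and $IF^{(k)}$ are the values on
the $K$ gated breathing phases of the pre-treatment 4D scan. The phases
are acquired minutes apart on the same day on the same (roughly unchanged)
tumor, so their spread measures what noise, resolution, and respiration do
to this feature in this patient — a patient-individualized noise floor.
$\delta$ is the treatment effect in units of that floor.

Both numerator and denominator are expressed as percentages of their
reference values. The defining equation of the statistic leaves this
scaling implicit; the percentage convention makes $\delta$ dimensionless,
invariant under any rescaling of the feature (units cancel), and of
magnitude $O(1\text{–}10)$ for realistic effects, consistent with the
published group statistics of the motivating study (property-tested in
`test-delta.R`).

The statistic is only meaningful if (a) the phase values are approximately
normal, so their SD is an interpretable dispersion measure, and (b) the
feature agrees between motion-compensated 4D and static 3D imaging, so the
4D-derived floor applies to the 3D-derived change. These are exactly the
two screens (Section 4).

## 2. The synthetic stated world

No study scans are available, so `phantom_io` generates them. The
generator is a stated world: its defaults are fixed to the acquisition
the method targets and are not tuning knobs.

* **Grid**: 32³ voxels at 4×4×4 mm (the reconstruction voxel of the
  emulated protocol); volumes/masks are NIfTI-1 float32/uint8.
* **Lesion**: ellipsoid, default semi-axes (22, 18, 15) mm ≈ 25 mL —
  between the ~86 mL central primaries and ~12 mL peripheral lesions the
  method has been applied to; uptake SUV 8 on background 1.
* **Heterogeneity**: sum of 30 seeded Gaussian blobs (SD 2 SUV, scale
  6 mm) inside the ellipsoid. Chosen over e.g. Gaussian random fields
  because it is cheap, reproducible from one integer seed, has analytic
  variance scaling, and moves AUC_CSH smoothly.
* **Degradation**: isotropic Gaussian PSF of FWHM 4.8 mm (the scanners'
  transverse resolution), then multiplicative Gaussian noise of CV 0.10.
  Full sinogram/Poisson simulation is deliberately out of scope: the
  method consumes reconstructed SUV images only, and the screens care
  about the *magnitude* of voxel-level variability, not its microscopic
  origin. The CV of a homogeneous region converges to the nominal value
  (property-tested).
* **Breathing**: the gated phase $k \in 0..K-1$ displaces the lesion by
  $(\cos^2(\pi k/K) - \tfrac12)\,A$ with peak-to-peak amplitude $A$
  (default 10 mm superior–inferior). $K$ is not fixed by the emulated
  protocol's published description; the default is $K = 8$ (a common
  gating choice) and every report carries the configured $K$. An
  `"irregular"` mode jitters per-phase amplitudes (CV 0.2), since
  irregular respiration is the known failure mode of 4D robustness.
* **Static 3D scan**: the time average of the displaced lesion over the
  cycle, then PSF and noise — so by linearity of the blur, the mean of
  the noiseless phases equals the noiseless static volume exactly
  (property-tested as correlation > 0.99).
* **Ground-truth masks** are the pre-blur ellipsoids (per phase at the
  displaced position). Segmentation produces its own masks from the
  blurred images; "manual" mode consumes the ground truth, mirroring
  expert contours that track the true extent.
* **Follow-up**: lesion-internal deviations from the lesion mean are
  shrunk by $(1-h)$, $h \in [0,1]$ ("homogenization"), optionally with
  volume and uptake rescaling. $h$ raises AUC_CSH, the planted
  counterpart of the clinical observation that homogenizing lesions
  recur locally. The default planted effect for LR cases is $h = 0.7$,
  **calibrated once** (as the acceptance design prescribes) so the
  resulting $\delta_{AUC\_CSH}$ of LR patients falls inside the
  clinically printed LR band (1.3–12.3, around a mean near 7); it was
  fixed before the acceptance tests were written and not revisited.

Determinism: every generator is a pure function of (spec, seed); texture
and noise come from separate derived sub-streams so the same lesion can be
re-imaged across scans with fresh noise.

## 3. Segmentation (COA)

The contrast-oriented algorithm thresholds at
$T = a\cdot mSUV70 + b\cdot BG$, where $mSUV70$ is the mean of voxels at
or above 70% of the search-region maximum and $BG$ a local background
estimate. The clinical calibration constants are not published with the
motivating study, so the package defaults to $a = b = 0.5$, exposes both,
and prints them in every result. The background is the mean SUV in a
2-voxel shell offset 2 voxels outside the bounding box of the 40%
isocontour — deterministic and phantom-verifiable. Post-processing keeps
the largest 26-connected supra-threshold component; no iteration, no hole
filling (the source description is silent on both). Consequences that are
tested rather than assumed: the threshold is linear under global intensity
scaling with an unchanged mask; raising $a$ never grows the mask; on an
undegraded phantom any $(a, b)$ with $BG < T \le$ uptake recovers the
truth exactly; blurred spheres ≥ 3× PSF FWHM are recovered within 15%
volume error. On *lumpy* lesions $mSUV70$ tracks the hot spots and COA is
legitimately tighter than the ground-truth ellipsoid — a known property of
contrast-based PET segmentation, visible in the test design.

## 4. Feature bank

Families: first-order (SUVmax, SUVmean, variance, skewness, kurtosis, CoV,
volume, AUC_CSH), GLCM, GLRLM, GLSZM, NGTDM. Three preprocessing variants:
raw, wavelet band-pass (`WF-`), equal-probability quantized (`Q-`);
first-order features always come from raw SUV.

* **AUC_CSH** uses the exact closed form $\overline{v}/v_{max}$ of the
  area under the cumulative SUV–volume histogram (no threshold grid).
  It is scale-free and weakly increases under shrinkage of deviations
  toward the mean — the mechanism $\delta_{AUC\_CSH}$ exploits
  (property-tested on random lesions).
* **Discretization**: fixed bin width W = 0.01 SUV, anchored at the mask
  minimum (level 1 at the minimum; an anchor at zero is exposed as the
  IBSI-style alternative). Equal-probability quantization uses 64 levels
  by default; the count is not fixed by the emulated protocol and is
  configurable and logged.
* **Texture matrices** are single merged matrices over the 13 unique 3D
  directions at Chebyshev distance 1 (the convention of the open-source
  toolbox lineage this bank follows), invariant under axis permutation
  (tested). Run percentage is normalized per direction,
  $RP = N_r/(N_{dir} N_{vox})$, so the single-direction closed forms
  (RP = 1 for unit runs) hold and RP stays in (0, 1].
* **Wavelet band-pass**: one-level 3D orthogonal DWT of the mask bounding
  box; the six mixed sub-bands (LLH…HHL) are weighted 2, the pure LLL and
  HHH weighted 1 (the 1:2 ratio), then inverse transform. Basis:
  Coiflet-1 by default, exposed. Boundary handling is *periodization*,
  not symmetric extension: with periodization the transform matrix is
  exactly orthogonal, so the unweighted round trip reconstructs the input
  to machine precision — a correctness identity the test suite asserts.
  For axes too short for a periodized coif1 matrix to remain orthogonal
  the code falls back to Haar on that axis (decided numerically at
  build, deterministic).
* **Undefined features** (e.g. GLCM on a single voxel, NGTDM without any
  in-mask neighborhood) become NA sentinels; downstream stages exclude
  the (patient, feature) record with a reason code instead of imputing.

## 5. Eligibility screens

* Normality: Shapiro–Wilk per (patient, feature) on the K phase values at
  α = 0.05; the feature passes when **strictly more than** 70% of
  evaluable patients pass ("more than 70%" read literally). Values
  constant across phases make the test undefined; they count as flagged
  passes — zero intrinsic variability is maximal stability — but such
  records are excluded at the δ stage anyway because σ = 0.
* Comparability: each patient's 3D value is paired with the **mean across
  phases** (the mean mirrors the time-averaged static acquisition;
  per-phase pooling would mix within- and between-patient variation).
  Two-sided Wilcoxon signed-rank per feature, BH-adjusted **across
  features within the screen** (the source describes the method, not the
  family; per-screen adjustment is the conservative reading). A
  significant shift is vetoed only if the Bland–Altman 95% CI of the mean
  percentage difference — per-pair difference as a percent of the pair
  mean, CI = mean ± 1.96·SD/√n — excludes zero. Fewer than 6 complete
  pairs refuses the screen (power floor, configurable).
* BH is implemented in the package (step-up with monotonicity) and tested
  against both a hand-computed example and `p.adjust`.

Calibration and power of both screens are acceptance-tested on synthetic
feature tables (type-I on null cohorts, ≥ 95% power against a 20% 3D/4D
shift at n = 30).

## 6. Outcome model

Group comparison uses Mann–Whitney U (exact when total n ≤ 20 and
tie-free, tie-corrected normal approximation otherwise), BH across
features. The logistic model reports full-data Wald coefficients; its
performance comes from B stratified bootstrap resamples (class counts
preserved — the imbalance adjustment; the exact scheme of the toolbox the
method originally used is not published, so this variant is *declared*,
not claimed identical). Out-of-bag cases are scored, the operating point
is Youden-optimal on the out-of-bag ROC, and AUC/sensitivity/specificity
are replicate means; replicates whose out-of-bag set lacks a class are
dropped and reported via `B_effective`. The ROC uses tie-grouped
thresholds and trapezoidal area, verified against the closed-form
two-Gaussian AUC $\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2})$. The
pipeline caps the model at the top `max_features = 2` candidates (ranked
by adjusted p, ties broken by group-median separation) — with cohort-scale
n a wider multivariate fit is rank-deficient; the clinical finding this
mirrors is a single-feature model. When nothing is significant the
pipeline still fits the best-ranked feature but flags the model
`exploratory`.

Which post-baseline scan enters $\Delta r$: the earliest available
(during-treatment if present, else after-treatment), configurable —
matching the workflow in which response PET is acquired as early as
feasible.

## 7. Numerical choices and degenerate inputs

* σ floor: records with relative phase SD < 0.1% are excluded with reason
  `sigma_floor` rather than producing near-infinite δ; |pre| or
  |mean(phases)| below 1e-8 gives `zero_reference`.
* NGTDM coarseness is capped at 1e6 on flat regions; busyness and
  contrast are 0 in the single-level case.
* GLCM correlation is defined as 1 when the matrix variance is 0.
* All-tied ROC scores yield the chance diagonal (AUC 0.5).
* Wilcoxon signed-rank with all-zero differences returns p = 1.
* Sub-seeds are derived from the master seed via a string hash
  (`derive_seed`), keeping every stream below 2³¹.

## 8. What a green test does and does not establish

The phantoms reproduce the *mechanisms* the method relies on — blur,
noise, periodic displacement, 3D-as-time-average, planted homogenization —
with controllable ground truth. They do **not** reproduce: Poisson count
statistics and reconstruction artifacts, irregular patient-specific
breathing baselines, inter-observer contouring variability, CT-based
attenuation effects, multi-scanner harmonization, or real biological
effect sizes. A green end-to-end acceptance run therefore establishes
that the pipeline recovers a planted effect of clinically printed
magnitude under its stated noise model — not that the clinical AUC of the
motivating study would replicate. The study's headline numbers come from
undeposited patient scans and are out of reach at desk scale by design.

## 9. Known limitations

* The feature bank implements the named subset (62 feature-variant
  combinations covering all 17 screen-surviving features), not the full
  135-feature appendix inventory; the bank is extensible by family.
* COA constants (a, b) and the clinical background ROI are defaults, not
  the (unpublished) clinical calibration; reports always state them.
* Survival endpoints (Kaplan–Meier, Cox) are out of scope; OS labels are
  carried as plumbing only.
* The NIfTI reader supports the axis-aligned single-file subset this
  pipeline writes (plus nibabel-written diagonal-affine files); it is not
  a general NIfTI implementation.
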