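# gdradiomics

Delta-radiomics response monitoring for FDG-PET of lung lesions with
respiratory-gated (4D) acquisitions.

## The problem

PET radiomic image features (IF) of a lung tumor change during
radio(chemo)therapy — but they also fluctuate for reasons that have nothing
to do with biology: image noise, limited scanner resolution, and breathing
motion ("intrinsic variability"). A treatment-induced change is only worth
acting on if it is large compared to that intrinsic variability, which
differs per feature *and per patient*.

This package implements a monitoring method that uses the feature
variability across the K bins of a pre-treatment respiratory-gated 4D PET
as a patient-individualized noise floor:

```
δ_IF = Δr_IF / σ_IF

Δr_IF = 100 · (IF_post − IF_pre) / |IF_pre|        relative change during treatment (%)
σ_IF  = 100 · SD(IF over 4D phases) / |mean(...)|  relative variability across phases (%)
```

δ is dimensionless and invariant under feature rescaling. Before δ is
trusted, every feature must pass a two-criterion eligibility screen:

1. **Normality across phases** — Shapiro–Wilk on each patient's K phase
   values; the feature passes if more than 70% of patients do.
2. **3D/4D comparability** — Wilcoxon signed-rank between each patient's
   static 3D value and the mean over phases, BH-adjusted across features;
   a significant shift is only confirmed if the Bland–Altman 95% CI of the
   mean percentage difference excludes zero.

Eligible per-patient δ values are then compared between outcome groups
(Mann–Whitney U, BH-adjusted) and fed into a binary logistic model whose
AUC/sensitivity/specificity are estimated by stratified (imbalance-adjusted)
bootstrap with out-of-bag scoring. The headline biomarker in this line of
work is δ of **AUC_CSH**, the area under the cumulative SUV–volume
histogram (fraction of lesion volume above each relative SUV threshold):
higher AUC_CSH = more homogeneous uptake, and lesions that *homogenize*
during therapy carry a higher local-recurrence risk.

Because no clinical scans ship with the package, a first-class synthetic
module generates gated PET phantoms: an ellipsoidal heterogeneous lesion
(seeded Gaussian-blob texture), blurred by a 4.8 mm FWHM PSF, degraded by
multiplicative Gaussian noise, displaced per phase by a cos² breathing
pattern, with a follow-up scan whose homogeneity change is planted per
outcome group.

## What is in the package

| Area | Functions |
|---|---|
| Data model & I/O | `image_volume`, `roi_mask`, `phase_series`, `patient_case`, `read_nifti`/`write_nifti`, `write_cohort`/`read_cohort` |
| Synthetic 4D phantoms | `lesion_spec`, `motion_spec`, `grid_spec`, `make_static_phantom`, `make_phase_series`, `simulate_followup`, `simulate_cohort` |
| Segmentation | `coa_segment` (contrast-oriented algorithm), `segment_phase_series`, `load_manual_mask` |
| Feature bank | `extract_features` / `extract_cohort`: first-order (incl. `auc_csh`), GLCM, GLRLM, GLSZM, NGTDM; raw, wavelet band-pass (`WF-`) and equal-probability quantized (`Q-`) variants; `discretize_fixed_bin` (W = 0.01 SUV), `equalize_quantize`, `wavelet_bandpass` |
| Eligibility screen | `normality_screen`, `comparability_screen`, `bh_adjust`, `select_eligible`, `screen_features` |
| Delta & outcome | `compute_delta`, `group_test`, `roc_curve`, `fit_logistic_bootstrap` |
| Orchestration | `validate_config`, `run_pipeline`, CLI at `inst/cli/gdr.R` |

## Worked example

```r
library(gdradiomics)

report <- run_pipeline(list(
  seed   = 42, output_dir = tempfile("gdr_demo_"),
  cohort = list(n = 10L, lr_fraction = 0.4),
  model  = list(B = 500L)))
print(report)
```

```
<pipeline_report>
  simulate  ok
  extract   ok
  screen    ok
  delta     ok
  model     ok
  eligible: AUC_CSH, Busyness, Coarseness, contrast, correlation, CoV, energy, entropy ...
  model AUC 0.956 (spec 0.946)
```

Ten synthetic patients (4 with local recurrence, planted follow-up
homogenization 0.7) are simulated, segmented, and run through the full
feature bank; 57 of 62 features pass both screens on this cohort. The
group tests on δ then rank the discriminating features:

```r
gt <- report$group_tests
head(gt[order(gt$p_adj, -abs(gt$median1 - gt$median0)), ], 5)
```

```
    feature_name  U       p  p_adj median1 median0
5    correlation  0 0.00952 0.0361  -13.71  -0.983
16    Q-contrast 24 0.00952 0.0361   13.30   0.977
18 Q-correlation  0 0.00952 0.0361  -12.39  -1.158
6            CoV  0 0.00952 0.0361  -10.60  -1.099
36   Variance_CM  0 0.00952 0.0361   -9.99  -0.876
```

`U = 0` / `U = 24` are the extreme Mann–Whitney statistics for 4-vs-6
groups (perfect separation of δ values); with n = 10 the exact two-sided p
floors at 0.0095, and BH adjustment keeps all of these at p_adj = 0.036 <
0.05. LR lesions homogenize (texture contrast and dispersion deltas are
strongly negative or positive depending on the feature's orientation).
The capped two-feature logistic model reaches an out-of-bag bootstrap AUC
of 0.956 and specificity 0.946 at the Youden operating point (B_eff = 447
of 500 resamples had both classes out of bag).

## Command line

```sh
GDR=$(Rscript -e 'cat(system.file("cli/gdr.R", package = "gdradiomics"))')
Rscript $GDR run      --config run.json
Rscript $GDR coa      --in vol.nii.gz --roi 3,3,3,30,30,30 --out mask.nii.gz --report coa.json
Rscript $GDR extract  --vol vol.nii.gz --mask mask.nii.gz --out features.csv
Rscript $GDR screen   --features features.csv --out screen_report.json
Rscript $GDR delta    --features features.csv --eligible screen_report.json --out deltas.csv
Rscript $GDR model    --deltas deltas.csv --outcome manifest.csv --label LR --out model.json
```

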