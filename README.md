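# rsivim

Multi-compartment modelling of multi-b-value diffusion-weighted MRI (DWI)
for quantitative tissue characterization, with breast-lesion diagnosis as
the motivating application. The package fits three signal models voxel-wise,
summarizes them over lesion ROIs, and runs the complete statistical layer a
diagnostic DWI study needs — group tests, per-parameter ROC, cross-validated
logistic models, and DeLong AUC comparisons — driven either by real NIfTI
volumes or by its own synthetic phantom/cohort generator.

## The models

For a voxel with baseline signal S₀ and diffusion weighting b (s/mm²):

- **Mono-exponential (ADC)** — S_b/S₀ = exp(−b·ADC), inverted exactly on
  the two-point subset (b = 0, 750).
- **IVIM (intravoxel incoherent motion)** —
  S_b/S₀ = (1−f)·exp(−b·Dt) + f·exp(−b·(Dt+Dp)), with tissue diffusion Dt,
  pseudo-diffusion Dp and perfusion fraction f ∈ [0,1]; fitted by bounded
  Levenberg–Marquardt over b ≤ 1000 with segmented initialization.
- **RSI (restriction spectrum imaging)** —
  S_b = C₁ + C₂·exp(−b·1.4×10⁻³) + C₃·exp(−b·10.2×10⁻³), a three-compartment
  decomposition with fixed diffusivities (restricted, hindered, free water);
  the non-negative contributions are estimated over all nine b-values, and
  fractions F_i = C_i/S₀ (F₁+F₂+F₃ = 1) plus the composite markers C₁C₂ and
  F₁F₂ are derived per voxel.

The synthetic module emulates a three-class cohort (malignant / benign /
normal fibroglandular tissue) from published group-level parameter moments,
with truncated-Gaussian lesion draws, per-voxel heterogeneity and Rician
(magnitude-MRI) noise.

## Worked example

```r
library(rsivim)

co <- generate_cohort(30, 15, 15, voxels_per_lesion = 24, snr = 50, seed = 42)

g <- group_comparison_table(co)
g[g$parameter %in% c("ADC", "Dt", "f"),
  c("parameter", "malignant_mean", "benign_mean", "chi2", "p_kw",
    "z_mal_vs_ben", "p_mal_vs_ben")]
#>   parameter malignant_mean benign_mean  chi2    p_kw z_mal_vs_ben p_mal_vs_ben
#> 1       ADC          1.018       1.269 11.01 0.00406        -3.37     0.000783
#> 2        Dt          0.672       0.840  7.82 0.02000        -2.89     0.004012
#> 4         f          0.227       0.274 12.75 0.00171        -3.25     0.001202

sel <- co$class %in% c("benign", "malignant")
roc_single_parameter(co$ADC[sel], co$class[sel], positive = "malignant")
#> $auc 0.811  $threshold 0.00113  $sensitivity 83.3  $specificity 80  $direction "<="

ev <- evaluate_models(co, contrast = c("benign", "malignant"), seed = 42)
round(ev$auc, 3)
#>      ADC     IVIM      RSI IVIM+RSI
#>    0.789    0.767    0.856    0.711
```

Reading the output: ADC and Dt are displayed in ×10⁻³ mm²/s, so a malignant
mean ADC of 1.018 is 1.018×10⁻³ mm²/s — lower than benign (1.269), the
expected restriction of dense tumours. The pairwise Mann–Whitney z/p columns
use the α = 0.0167 multiple-comparison convention. The ROC row says ADC
separates malignant from benign lesions with AUC 0.811 at an optimal
threshold of 1.13×10⁻³ mm²/s ("≤": lower values call malignant). The model
AUCs are 5-fold stratified cross-validated means; at this small cohort size
the 11-feature hybrid model can trail the single-feature models — with
study-sized cohorts it matches or beats them.

An end-to-end pipeline is available as functions
(`cmd_simulate`, `cmd_fit`, `cmd_analyze`) and as a thin command-line
front end (`inst/cli/rsivim.R`).

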