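---
title: "Multi-compartment diffusion modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment diffusion modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsivim)
```

## The signal models and their assumptions

A multi-b-value DWI acquisition measures the magnitude signal of one voxel
at increasing diffusion weightings b (s/mm²); here the nine-point breast
protocol b = 0, 50, 100, 250, 500, 750, 1000, 1500, 2000. Three nested
views of the decay are fitted:

**Mono-exponential.** S_b/S₀ = exp(−b·ADC) collapses all water pools into a
single apparent diffusion coefficient. Following the definition of the ADC
on the (0, 750) pair, `fit_mono_adc()` inverts the model exactly on those
two points: ADC = ln(S₀/S₇₅₀)/750. With two observations this *is* the
linear least-squares solution of the log-linearized model, so nothing is
lost relative to a regression formulation. Noise can make S₇₅₀ > S₀; the
negative estimate is clipped to 0 and flagged rather than propagated.

**IVIM.** S_b/S₀ = (1−f)·e^(−b·Dt) + f·e^(−b·(Dt+Dp)) separates slow tissue
diffusion (Dt) from capillary pseudo-diffusion (Dt+Dp) weighted by the
perfusion fraction f. The model assumes the perfusion pool is fully
attenuated by moderate b, which is why it is fitted only on the b ≤ 1000
subset — the high-b points carry non-Gaussian tissue effects the
bi-exponential does not describe. The joint fit is notoriously
ill-conditioned: Dp is only identified through the low-b shoulder, and for
f → 0 not at all.

**RSI.** S_b = C₁ + C₂·e^(−b·1.4×10⁻³) + C₃·e^(−b·10.2×10⁻³) fixes the
compartment diffusivities (restricted/intracellular at 0, hindered/
extracellular at 1.4×10⁻³, free water and flow at 10.2×10⁻³ mm²/s) and
estimates only the non-negative contributions, over all nine b-values.
Fixing the diffusivities makes the inverse problem *linear*, which is the
model's practical appeal: 9 equations, 3 unknowns, full rank. Fractions
F_i = C_i/S₀ (renormalized so F₁+F₂+F₃ = 1 exactly) and the per-voxel
products C₁C₂ and F₁F₂ are derived, the products being empirical composite
markers that reward voxels strong in both the restricted and hindered pools.

Units: all diffusivities are stored in mm²/s throughout the package; only
the report layer rescales ADC and Dt to the conventional ×10⁻³ display.
This removes a whole class of unit mistakes from the computational path.

## Numerical choices in the fits

- **IVIM bounds**: Dt ∈ [10⁻⁵, 3×10⁻³] mm²/s (tissue water), Dp ∈ [10⁻³,
  0.5] mm²/s (pseudo-diffusion is 1–2 orders faster), f ∈ [0, 1] by
  definition. Bound enforcement is what guarantees the fitted f can never
  leave [0, 1] under any noise.
- **IVIM initialization** is segmented: a log-linear regression over b ≥ 250
  (where the perfusion term is negligible) gives Dt⁰ and, extrapolated to
  b = 0, the tissue amplitude A; f⁰ = clip(1−A, 0.01, 0.6); Dp⁰ = 0.02
  mm²/s. The joint bounded Levenberg–Marquardt refinement then starts close
  to the basin. Two alternative Dp starts (5×10⁻³, 0.1) guard against the
  flat Dp direction; the lowest-residual solution wins. Convergence control:
  ftol = ptol = 10⁻¹⁵, 500 iterations. On noiseless input the round-trip
  error is at machine precision (tested to < 10⁻⁴ relative across a 5×5×5
  grid spanning the class moments ± 2 SD).
- **Degenerate IVIM inputs**: a purely mono-exponential voxel fits with
  f ≈ 0, and Dp is then meaningless — the result carries a
  `dp_unidentifiable` flag (f < 0.01). Parameters landing on a box bound
  are flagged `at_bound`; callers can filter on flags without losing the
  best-iterate values.
- **RSI**: fitted on the *raw* signal (its left-hand side is S_b, not
  S_b/S₀), by bounded Levenberg–Marquardt with non-negativity. A projected
  LM iterate can stall marginally short of the constrained optimum when a
  contribution sits on the zero bound, so the solution is refined by an
  exact active-set step: with three unknowns, the non-negative optimum is
  the best feasible unconstrained least-squares solution over the seven
  possible supports, which is enumerated directly. The result agrees with
  an independent NNLS solver to 10⁻⁶ on every tested voxel.
- **Missing values**: unfittable voxels (zero baseline, all-zero signal,
  too few usable points) carry `NA`, which propagates NaN-semantics — ROI
  summaries average the remainder.

## What the synthetic generator emulates — and what it does not

Because no patient data are available, the generator stands in for them
with the documented generative law: per lesion, the six generative
parameters (Dt, Dp, f, C₁, C₂, C₃) are drawn from class-specific Gaussians
(published group moments for malignant, benign and normal fibroglandular
tissue) truncated to the fitting bounds by rejection; per voxel, a 5%
multiplicative jitter emulates intra-lesion heterogeneity; the noiseless
voxel signal is the IVIM forward model scaled so the three-compartment
decomposition holds at b = 0 (S₀ = C₁+C₂+C₃); Rician noise
(√((S+n₁)²+n₂²), SD = S₀/SNR) corrupts the magnitudes. The default SNR of
50 at b = 0 is typical of clinical breast DWI; the default cohort
composition (116 malignant / 41 benign / 41 normal) mirrors the study the
class moments come from.

One signal cannot be simultaneously an exact bi-exponential in (Dt, Dp, f)
*and* an exact fixed-diffusivity tri-exponential in (C₁, C₂, C₃). The
generative law therefore makes the IVIM triple and the b = 0 amplitude the
recoverable ground truth, while fitted ADC and the fitted RSI decomposition
are *emergent* quantities — deterministic consequences of the generative
parameters, close to but not equal to the class moments they were seeded
from. Tests reflect this: the SNR → ∞ convergence invariant is asserted for
Dt, Dp, f (10⁻³ relative at SNR = 10⁶, jitter off), and the closed-form
two-Gaussian AUC oracle is checked for ADC, whose emergent distribution
tracks its generative moments closely (observed agreement ≈ 0.003 on the
default cohort, band ± 0.05).

Passing tests on this generator therefore demonstrate correctness of the
fitting and statistical machinery under a *known, well-specified* data law.
They do not demonstrate robustness to what real breast DWI adds: EPI
distortion, fat-suppression failure, motion, partial volume at lesion rims,
non-mass morphologies, or T2 shine-through — all explicitly out of scope.

## Agreement and statistics layer

- **Overlap**: DSC = 2|A∩B|/(|A|+|B|); reader A is the reference, so
  recall = |A∩B|/|A| and precision = |A∩B|/|B| (the identity
  DSC = 2PR/(P+R) is property-tested). The simulated second reader flips
  only boundary voxels (6-neighborhood) with a configurable probability.
- **ICC**: the variant is not dictated by convention alone, so the package
  uses ICC(A,1) — two-way random effects, absolute agreement, single
  measures — the standard choice for two interchangeable raters, with the
  McGraw–Wong F-based 95% CI, computed from ANOVA mean squares. The
  implementation is validated against an independent reference
  implementation on a frozen fixture. Bands: 0.81–1.00 excellent,
  0.61–0.80 good, 0.41–0.60 moderate, 0.21–0.40 fair, 0.01–0.20 slight.
- **Rank tests**: Kruskal–Wallis (α = 0.05) for the three-class omnibus;
  Mann–Whitney (α = 0.0167, guarding the three pairwise comparisons) for
  pairs. The reported z is the tie-corrected standardized U without
  continuity correction (the convention of printed z-values); the p-value
  is exact (full enumeration of the U distribution) whenever
  n₁·n₂ ≤ 400 and the data are tie-free, and continuity-corrected normal
  otherwise — the correction keeps exact and approximate p within 0.01 of
  each other from n ≈ 15 upward.
- **ROC**: empirical, AUC = U/(n₁n₂) (identity property-tested to 10⁻¹²);
  direction auto-chosen so AUC ≥ 0.5 and reported as ">" (higher = positive)
  or "≤"; the operating threshold maximizes Youden's J, first maximizer on
  ties. Youden is used because tabulated thresholds in this literature are
  consistent with it and no alternative rule is stated.
- **Diagnostic models**: plain maximum-likelihood logistic regression on
  the standard feature sets (ADC; Dt+Dp+f; the eight RSI parameters; their
  union), under stratified 5-fold CV with a single seed controlling the
  fold shuffle. Features are standardized with training-fold statistics
  only (no leakage). Separation is not penalized away: the non-convergent
  fold is flagged and the best-iterate scores are used.
- **DeLong**: placement-value covariance on *pooled out-of-fold scores*.
  Pooling is a deliberate choice — per-fold DeLong at these sample sizes is
  hopelessly underpowered, and the pooled scores are the quantity the CV
  procedure actually produces for each lesion exactly once; per-fold AUC
  lists are exported alongside for transparency. Degenerate comparisons
  (identical or monotone-equivalent scores) return p = 1 by construction.

## Problem sizes

The shipped tests exercise: 1,000-voxel batches for the fraction-sum and
bound-enforcement properties; 5×5×5 noiseless round-trip grids; 50-dataset
rank-identity sweeps; 2,000 null simulations for Mann–Whitney and 500 for
DeLong type-I calibration; and a full 157-lesion cohort at 64 voxels/lesion
for the generative AUC check. These sizes give Monte-Carlo error comfortably
inside each assertion's tolerance while keeping the whole suite around a
minute on one core.

## Known limitations

- The generator's per-voxel jitter is multiplicative and independent across
  parameters; real lesion heterogeneity is spatially structured.
- The phantom assigns class-mean parameters to every voxel of a region
  (by design, so noiseless regional recovery is exact) — it is not a
  heterogeneity phantom.
- Rician noise is the correct single-coil magnitude law; modern
  multi-channel reconstructions are closer to non-central chi.
- The mono-exponential ADC uses only (0, 750); acquisitions lacking b = 750
  cannot produce ADC maps in this package.
- Fitted RSI contributions from IVIM-shaped synthetic signals are emergent
  effective values; cohort-level RSI summaries should not be read as
  estimates of the generative class moments.
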