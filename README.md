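# dmdbold

Spatiotemporal feature extraction for resting-state fMRI ROI time series via
exact dynamic mode decomposition (DMD), with stability-style feature
selection and a linear-SVM benchmark — aimed at studies that look for brain
regions whose oscillation amplitude differs between a patient group and
controls (e.g. schizophrenia cohorts parcellated into Schaefer regions).

## What it computes

A subject's T × R ROI matrix (T time points every Δt seconds, R regions) is
modelled as a one-step linear system `X' ≈ A X` and decomposed with exact
DMD using scaled modes: thin SVD `X = U S V*`, projected propagator
`Ã = U* X' V S⁻¹` rescaled as `Â = S^(-1/2) Ã S^(1/2)`, eigendecomposition
`Â Ŵ = Ŵ Λ`, and modes `Φ = X' V S⁻¹ W` with `W = S^(1/2) Ŵ`. Each mode
φᵢ has a frequency `fᵢ = |Im log λᵢ| / (2π Δt)`, an amplitude
`Pᵢ = ‖φᵢ‖²`, and per-region powers `Pᵢⱼ = |φᵢⱼ|²`.

On top of the decomposition the package provides:

- **Features** — per-region mean amplitudes `featureⱼ = Σᵢ Pᵢⱼ / M` over
  the modes retained in the infra-slow 0.01–0.1 Hz band, plus sub-band
  spliced variants (k equal-width bands, R·k features).
- **Abnormal-region selection** — repeated LASSO regressions of features on
  the 0/1 group label at fixed γ = 0.2, intersection of the selected sets
  across repeats, mean coefficients β̄ (sign = direction of the group
  difference), and a label-permutation screen at α = 0.05.
- **Benchmarking** — linear SVM under 3 × 10 stratified cross-validation
  (30 sets of accuracy/precision/recall/F1/specificity) for chance-label,
  all-feature, per-fold-LASSO and intersection feature sets on shared fold
  divisions, with permutation comparison of metric distributions.
- **Reconstruction & prediction** — the explicit signal model
  `x(t) = Φ Λ^(t/Δt) Φ⁺ x(0)`, per-horizon out-of-sample RMSE.
- **Connectivity** — functional connectivity (FC, Pearson correlation of
  region time courses) versus the mode-sequence correlation matrix (phiC,
  correlation of mode rows), which closely tracks FC.
- **Synthetic cohorts** — a generator of band-limited oscillatory cohorts
  with planted region- and band-specific group effects, and exact
  linear-dynamical-system cohorts used as decomposition oracles.

See the vignette (`vignettes/dmd-mean-amplitude-features.Rmd`) for the
methods account: model assumptions, parameter meanings and defaults,
numerical choices, and what the synthetic cohorts do and do not emulate.

## Worked example

Generate a 40-subject cohort with two planted effects — region 7 elevated in
the 0.01–0.04 Hz band, region 21 suppressed in 0.04–0.07 Hz — then recover
them:

```r
library(dmdbold)

spec <- cohort_spec(
  n_per_group = 20, R = 30, T = 140, dt = 2,
  effects = list(effect_spec(7,  c(0.01, 0.04), +1, 0.6),
                 effect_spec(21, c(0.04, 0.07), -1, 0.6)),
  seed = 42)
cohort <- generate_sinusoid_cohort(spec)
cohort
#> <dmd_cohort> 40 subjects (20 patients / 20 controls), 140 x 30, dt = 2 s

dec <- exact_dmd(build_snapshots(cohort$subjects[[1]]))
dec
#> <dmd> 30 modes over 30 regions, dt = 2 s; freq range [0.01467, 0.25] Hz
length(band_filter_modes(dec, c(0.01, 0.1))$indices)
#> [1] 20

features <- assemble_feature_table(cohort, mode = "full")
sel <- repeated_lasso_selection(features,
                                lasso_config(gamma = 0.2, n_repeats = 50, seed = 1))
sel <- call_abnormal_regions(sel, features, alpha = 0.05, B = 1000, seed = 2)
sel$report
#>   feature feature_name region band network mean_coefficient     p_value abnormal
#> 1       7         R007   R007 full  SomMot       0.16834054 0.000999001     TRUE
#> 2      21         R021   R021 full  Limbic      -0.09874416 0.000999001     TRUE
```

Both planted regions — and only they — survive the repeated-LASSO
intersection and the permutation screen. The positive β̄ for region 7 says
the patient group's mean amplitude is higher there; the negative β̄ for
region 21 says it is lower, matching what was planted. The p-values sit at
the permutation lower bound 1/(B+1).

The mode-sequence correlation tracks functional connectivity even on this
small noisy cohort:

```r
fc   <- functional_connectivity(cohort$subjects[[1]])
phic <- mode_sequence_correlation(dec, band_filter_modes(dec, c(0.01, 0.1)))
unlist(compare_connectivity(phic, fc))
#>    pearson_r         rmse      n_pairs
#>   0.92826243   0.09290388 435.00000000
```

On noiseless periodic cohorts at full 300-region scale the agreement rises
above r = 0.99.

`run_pipeline(cohort, pipeline_config(...))` chains all stages (features →
selection → SVM benchmark → connectivity) and optionally writes every
artifact as TSV/JSON with provenance.

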