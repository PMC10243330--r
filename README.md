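# ivimopt

Design and evaluation of diffusion-MRI b-value acquisition schemes for the
intravoxel incoherent motion (IVIM) model, with segmented fitting, Monte-Carlo
error scoring, greedy scheme optimization, and voxelwise parametric mapping.

## The problem

IVIM separates capillary perfusion from thermal diffusion in
diffusion-weighted MRI through the biexponential decay

    S(b)/S(0) = f exp(-b D*) + (1 - f) exp(-b D)

with the tissue diffusion coefficient *D* (mm²/s), the pseudo-diffusion
coefficient *D\** (mm²/s) and the perfusion fraction *f*. The precision of
the fitted parameters depends heavily on *which* b-values are acquired, and
no consensus acquisition protocol exists. `ivimopt` is for MR physicists and
image-analysis researchers who want to (a) score a candidate b-value scheme
by the total relative error σ_tot = σ_D + σ_f + σ_D\* of segmented-fit
estimates over simulated Rician-noise acquisitions, (b) optimize a scheme by
greedy forward selection with frequency aggregation and backward
elimination under Low/Medium/High perfusion regimes, and (c) apply the same
segmented fit voxelwise to 4D NIfTI volumes (with a synthetic digital brain
phantom standing in for scanner data).

The segmented fit estimates *D* by a log-linear fit above the 200 s/mm²
threshold, *f* from the back-extrapolated intercept (negative values
discarded), and *D\** by bounded nonlinear least squares below the threshold
(constraint [0, 0.1] mm²/s; [0, 0.2] in tumor tissue).

## Worked example

Score the optimized 13-b-value scheme against a clinical non-optimized
7-b-value protocol in the Medium perfusion regime (D = 1.5e-3 mm²/s,
D\* = 15e-3 mm²/s, f = 0.30) at the 50 dB noise level:

```r
library(ivimopt)
regimes <- ivim_regimes()
lib     <- scheme_library()
snr50   <- snr_from_db(50)   # 50 dB -> linear SNR 316.2

opt <- monte_carlo_error(regimes$Medium, lib[["b-opt(13b)-Medium"]],
                         snr = snr50, n_simulations = 2000, seed = 7)
ref <- monte_carlo_error(regimes$Medium, lib[["b-CNAO(7b)"]],
                         snr = snr50, n_simulations = 2000, seed = 7)
opt
#> <ivim_error_report> Medium on b-opt(13b)-Medium @ SNR 316.228 (n = 2000, seed = 7)
#>   sigma_D = 0.0150  sigma_f = 0.0456  sigma_D* = 0.0663  sigma_tot = 0.1269 (se 0.0010)
#>   retained 2000 | f-discarded 0 | non-converged 0 | D* at bound 0
ref
#> <ivim_error_report> Medium on b-CNAO(7b) @ SNR 316.228 (n = 2000, seed = 7)
#>   sigma_D = 0.0261  sigma_f = 0.0644  sigma_D* = 0.1222  sigma_tot = 0.2126 (se 0.0008)
#>   retained 2000 | f-discarded 0 | non-converged 0 | D* at bound 0
percent_reduction(opt$sigma_tot, ref$sigma_tot)
#> [1] 40.33742
```

Reading: with the optimized scheme, every per-parameter relative RMS error
roughly halves (e.g. σ_D\* drops from 12.2% to 6.6%), and the total relative
error falls by 40% — 2000 curves per scheme, none discarded, no D\* estimate
stuck at a constraint bound.

Other entry points: `optimize_scheme()` / `build_frequency_table()` /
`select_optimal_scheme()` for the forward search, `backward_eliminate()` and
`reducible_size()` for scheme reduction, `cross_regime()` for
regime-mismatch robustness, and `generate_phantom()` + `fit_volume()` +
`roi_summary()` for volumetric mapping. A thin CLI (`exec/ivimopt`) exposes
these as subcommands over YAML/JSON configurations; the methods vignette
(`vignettes/bvalue-scheme-optimization.Rmd`) documents the model, the
numerical choices and their rationale.

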