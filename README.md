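# spincascade

Analysis toolkit for femtosecond pump–probe X-ray spectroscopy of
photoexcited heme proteins — for spectroscopists reducing Fe Kα/Kβ X-ray
emission (XES) and Fe K-edge absorption (XANES) delay scans into spin-state
assignments and cascade kinetics.

Photoexcitation of a ferric heme launches a relaxation cascade through
metal spin states, S = 1/2 → 3/2 → 5/2 → 1/2, visible in three X-ray
observables: the Kα1 line width (which grows with the number of unpaired 3d
electrons), the Kβ mainline/Kβ′-sideband intensity pattern, and the
transient edge absorption that tracks the structurally domed population.
The package implements the full chain:

* **Line shapes** — asymmetric pseudo-Voigt profiles
  `I(E) = A[η L(E) + (1−η) G(E)]` with sigmoidally varying width
  `Γ(E) = 2Γ₀ / (1 + e^{−a(E−E₀)})`; joint Kα1/Kα2 doublet fits and numeric
  FWHM extraction (`apv_profile`, `fit_doublet`, `numeric_fwhm`,
  `delta_fwhm`).
* **Transients** — laser-on minus laser-off difference spectra,
  normalization, shift/scale fingerprint matching against reference
  difference spectra, and energy-window integration into kinetic traces
  (`make_transient`, `best_shift`, `match_spin`, `integrate_window`).
* **Kinetics** — exact Gaussian-IRF-convolved exponentials
  `H(t; τ) = ½ exp(σ²/2τ² − (t−t₀)/τ) erfc((σ/τ − (t−t₀)/σ)/√2)`,
  closed-form sequential-cascade populations, 1–3 component trace fitting
  with residual-resampling bootstrap confidence intervals, weak-component
  flagging, and AICc model comparison (`emg_response`,
  `cascade_populations`, `fit_trace`, `compare_models`).
* **Yield accounting** — depth-averaged Beer–Lambert photoexcitation
  fraction versus the transient-amplitude estimate, with the factor-of-2
  consistency check (`excited_fraction`, `observed_fraction`,
  `consistency_ratio`).
* **Synthetic data** — a generator that emulates the spectral and kinetic
  structure of the cascade (species line models, counting-like noise,
  seeded determinism), so the whole pipeline is validated by parameter
  recovery (`species_spectrum`, `synth_timeseries`, `synth_kinetic_trace`).
* **Pipeline** — `run_pipeline()` sequences simulate → line-shape fits →
  transients → kinetic fits → classification → yield from one (YAML-able)
  config, writing TSV tables plus an MD5 manifest; `report()` prints the
  fit-table summary.

See the methods vignette (`vignettes/spincascade-methods.Rmd`) for the
models, defaults and design decisions.

## Worked example

Simulate one noisy XANES kinetic trace at the cascade ground truth
(IRF 0.14 ps, τ₁ = 0.61 ps with weight 0.70, τ₃ = 8.7 ps with weight 0.30),
fit it, and extract the Kα1 broadening from a synthetic laser-on/off pair:

```r
library(spincascade)

truth <- cascade_params(t0_ps = 0, irf_fwhm_ps = 0.14, tau1_ps = 0.61,
                        tau3_ps = 8.7, f_exc = 1)
w <- weights_from_amplitudes(0.70, 0.30, truth)
trace <- synth_kinetic_trace("xanes_amplitude", truth, weights = w,
                             noise_level = 0.05, seed = 42)
fit <- fit_trace(trace, n_components = 2, n_boot = 200, seed = 1)
fit
#> <biexp_fit> 'XANES@7125.3eV': t0 = 0.01204 ps, IRF FWHM = 0.1544 ps
#>   tau1 = 0.4851 ps (a = 0.746)
#>   tau2 = 7.715 ps (a = 0.3126)
#>   baseline 0.01183, residual rms 0.04474, n_boot 200
round(fit$ci68[, c("tau1_ps", "tau2_ps", "irf_fwhm_ps")], 3)
#>     tau1_ps tau2_ps irf_fwhm_ps
#> 16%   0.400   6.182       0.137
#> 84%   0.547   9.705       0.173

fit_off <- fit_doublet(species_spectrum("kalpha", "LS"))
fit_on  <- fit_doublet(species_spectrum("kalpha", "HS"), init = fit_off$params)
fit_off
#> <doublet_fit> Kalpha1 6404.000 eV (FWHM 2.207 eV), Kalpha2 6391.000 eV, rms 2.1e-11
delta_fwhm(fit_on, fit_off)$delta_fwhm_ev
#> [1] 0.7
```

One 5%-noise realization scatters around the truth (0.485 vs 0.61 ps for
the fast constant here); the bootstrap 68% intervals quantify that scatter,
and the truth is recovered by ensemble medians — which is exactly what the
acceptance script measures. The 0.7 eV laser-on broadening is the full
low-spin → high-spin Kα1 FWHM difference at complete excitation.

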