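---
title: "Models and methods: line shapes, cascade kinetics and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: line shapes, cascade kinetics and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spincascade)
```

# The analysis problem

Photoexciting the heme of a ferric (Fe(III)) heme protein launches an
electronic relaxation cascade through metal spin states: the low-spin
(LS, S = 1/2) ground state is promptly promoted, an intermediate-spin
(IS, S = 3/2) state is populated within the instrument response, decays in
a few hundred femtoseconds to the high-spin (HS, S = 5/2) state, which
returns to the ground state on a ~10 ps time scale. Femtosecond X-ray
spectroscopy sees this cascade through three observables:

* **Fe Kα emission** (2p→1s): the Kα1 line width grows with the number of
  unpaired 3d electrons, so the laser-on/laser-off Kα1 FWHM difference is a
  spin thermometer;
* **Fe Kβ emission** (3p→1s): the mainline (~7058 eV) loses intensity and
  blue-shifts while the Kβ′ sideband (~7043 eV) grows with spin — the
  classic fingerprint used for spin assignment by comparison with reference
  difference spectra;
* **Fe K-edge XANES**: the transient absorption at the edge (7125.3 eV)
  tracks the structurally domed (IS + HS) population.

This package implements the full reduction and inference chain for such
experiments — line-shape fitting, transient construction, fingerprint
matching, IRF-convolved kinetic fitting with bootstrap uncertainties, and
excitation-yield accounting — together with a synthetic-data generator that
reproduces the statistical structure of the measurements, so that every
stage of the pipeline is validated end-to-end by parameter recovery.

# Emission line model

A single emission line is an *asymmetric pseudo-Voigt*: a linear mix of
unit-height Gaussian and Lorentzian profiles whose common width varies
sigmoidally across the line,

$$ I(E) = A\left[\eta\,L(E) + (1-\eta)\,G(E)\right],\qquad
   \Gamma(E) = \frac{2\Gamma_0}{1 + e^{-a(E-E_0)}} . $$

A single asymmetry rate $a$ (1/eV) skews the profile — positive $a$
broadens the blue wing — and $a=0$ recovers the symmetric pseudo-Voigt of
FWHM $\Gamma_0$ exactly. Because the observable reported everywhere is a
*measured* width, `numeric_fwhm()` extracts the FWHM numerically (maximum
location by golden-section search, half-maximum crossings by bisection to
1e-9 eV) rather than quoting $\Gamma_0$.

The Kα doublet (Kα1 at 6404 eV, Kα2 at 6391 eV, peak ratio ≈ 2:1) is always
fit jointly with a shared constant baseline, since the lines overlap at
their 13 eV separation (`fit_doublet()`, bounded Levenberg–Marquardt,
weights $1/\sigma^2$ when uncertainties exist). For low-signal laser-on
spectra the recommended mode seeds the fit from the laser-off result and
frees only the amplitudes and widths (`fix =` centers, mixing and
asymmetry); with noiseless or strong data the full-free fit is used. Which
parameters to share between on and off fits is a genuinely open choice; the
shared-shape default trades a possible small bias for much better
conditioning at low excitation fractions.

# Cascade kinetics

The sequential scheme GS → IS → HS → GS driven by a Gaussian pump of
integrated excited fraction $f$ has closed-form populations built from the
exponentially modified Gaussian

$$ H(t;\tau) = \tfrac12 \exp\!\left(\frac{\sigma^2}{2\tau^2} -
   \frac{t-t_0}{\tau}\right)
   \operatorname{erfc}\!\left(\frac{\sigma/\tau-(t-t_0)/\sigma}{\sqrt2}\right),
   \qquad \sigma = \frac{\mathrm{FWHM}_{\mathrm{IRF}}}{2\sqrt{2\ln2}}, $$

the exact convolution of the unit-area Gaussian IRF with a causal
exponential decay:

$$ N_{IS} = f\,H(t;\tau_1), \qquad
   N_{HS} = f\,\frac{\tau_3}{\tau_3-\tau_1}\left[H(t;\tau_3)-H(t;\tau_1)\right]. $$

`emg_response()` evaluates $H$ in an overflow-safe form: for
$z = (\sigma/\tau - u/\sigma)/\sqrt2 \ge 0$ the identity
$H = \tfrac12\,\mathrm{erfcx}(z)\,e^{-u^2/2\sigma^2}$ cancels the exponents
exactly (with an asymptotic series for $\mathrm{erfcx}$ beyond $z=20$,
where the library rational approximation overflows); for $z<0$ the direct
form has a negative exponent and is safe. The degenerate case
$\tau_1=\tau_3$ is evaluated by a symmetric finite-difference limit when
the constants agree to 1e-6 relative. Both branches are tested against
adaptive-quadrature convolution (1e-8) and explicit Runge–Kutta integration
of the rate equations (1e-6).

Observed traces are fit as IRF-limited-rise multiexponentials
$y(t) = b + \sum_i a_i H(t;\tau_i)$ (`fit_trace()`), which is how such
kinetics are conventionally reported (a table of $\tau_r$, $\tau_i(a_i)$);
the cascade closed forms serve generation and interpretation (the fast
amplitude maps onto the IS branch, the slow one onto HS). Time constants
and the IRF width are optimized in log space, making positivity structural
and letting the same code fit one to three components.

## Uncertainties and model comparison

68% confidence intervals come from a seeded residual-resampling bootstrap
(default 200 replicates): residuals of the converged fit are resampled with
replacement, added to the fitted curve, and the model refit. This choice is
itself calibrated: over 300 simulated experiments at 5% peak noise the 68%
interval for $\tau_1$ covers the generating value 65.7% of the time (the
acceptance suite asserts 60–76%).

Each fit also carries linearized (Gauss–Newton covariance) sigmas, computed
by SVD with floored singular values so that directions the data do not
constrain produce large — not failed or falsely small — uncertainties.
These two routes answer different questions. The bootstrap describes the
sampling variability of a *well-specified* fit. For overfitting diagnosis
it is the wrong tool: resampling residuals around an overfitted curve
regenerates data that contain the spurious component, so the bootstrap
re-finds it. `weak_components()` therefore applies the conventional
consistent-with-zero test, $|a_i| \le z\,\sigma_{a_i}$ at the two-sided 95%
level by default, to the covariance sigmas (a bootstrap 68% interval
spanning zero also counts). On 100 simulated two-component datasets the
spurious third component of a triexponential fit is flagged in 94% of runs
with no false flags on the true components — mirroring the physical
analysis, where a triexponential control fit returns a weak, ill-determined
middle component and the biexponential description is retained.
Triexponential control fits should be seeded from the converged
biexponential fit plus a near-zero middle component (as the acceptance
suite does); free-running three-component fits fall into local minima that
split a real component in two. Fits whose adjacent time constants agree
within a factor of two are flagged `collinear_taus`: their amplitudes are
not individually identifiable.

`compare_models()` ranks fits of the same trace by the small-sample
corrected information criterion
$\mathrm{AICc} = n\log(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$ on the
weighted residuals and reports the weak-component flags per fit.

# Transients, fingerprints and windows

`make_transient()` restricts to the grid overlap, resamples the laser-off
spectrum linearly onto the laser-on grid and subtracts; nothing is smoothed
anywhere in the pipeline, because smoothing biases width extraction.
`best_shift()` matches one difference spectrum onto another by a 0.05 eV
grid search with parabolic refinement over shift (and least-squares
amplitude scale), the quantitative version of the overlay argument used to
compare a measured transient with reference high-spin-minus-low-spin
difference spectra that must be red-shifted by 1–2 eV to account for
species edge shifts. A positive shift moves the reference to higher energy.
`match_spin()` ranks a labelled library by residual RMS and raises an
ambiguity caveat when the top two residuals are within 10% — the honest
outcome for S = 3/2 vs S = 5/2 fingerprints, which differ too little at
realistic noise for the ranking to be meaningful on its own.

The default integration windows for Kα lobe kinetics are
[6402, 6405] eV (negative lobe) and [6405, 6408] eV (positive lobe),
centred on the 6404/6406 eV features; both are exposed in the pipeline
configuration.

# The synthetic-data generator

The generator exists because the raw beamline data are not publicly
deposited; it emulates the *statistical structure* the analysis relies on,
with every default exposed:

| parameter | default | why |
|---|---|---|
| Kα1 / Kα2 centers | 6404 / 6391 eV | canonical Fe Kα energies |
| LS Kα1 FWHM | 2.2 eV | free parameter (instrument-convolved width); set so the transient lobes fall at the observed 6406/6404 eV (see below) |
| HS − LS Kα1 FWHM excess | 0.7 eV | the measured laser-on broadening; the width law is linear in the number of unpaired electrons up to S = 3/2 and constant beyond |
| asymmetry rate | 0.1 + 0.15 per spin step | blue-wing-weighted broadening; keeps growing with spin (below) |
| Kβ mainline / sideband | 7058 / 7043 eV | canonical energies; per spin step 10% of mainline amplitude transfers to the sideband and the mainline shifts +0.3 eV (sign pattern is physical, magnitudes are free) |
| energy grids | 6380–6420, 7020–7080 eV at 0.2 eV | typical dispersive-spectrometer coverage; spacing is a free parameter |
| delays | −1 to 1 ps at 0.05 ps + 30 log-spaced to 50 ps | linear coverage of the rise, log coverage of the decay |
| cascade truth | 0.14 / 0.61 / 8.7 ps, f = 0.3 | the XANES-row constants; excited fraction of order the fluence accounting |
| spectrum noise | $\sigma(E) = \nu\, S_{max}\sqrt{S(E)/S_{max}}$ | counting-like heteroscedasticity |

Two line-model choices deserve justification. First, the LS width default
is 2.2 eV rather than a literature-style 2.8 eV: the positive/negative
transient lobe positions scale with the line width, and 2.8 eV places the
positive lobe near 6406.9 eV where the observed feature sits at 6406 eV;
2.2 eV reproduces 6406/6404 eV on the default grid. Second, the FWHM excess
saturates at S = 3/2 (IS and HS have equal *total* broadening) but the
asymmetry rate keeps growing, so the HS excess width sits further onto the
blue wing than the IS one. That distributes relatively more HS signal into
the positive lobe, which is why the positive-lobe integral rises more
slowly than the negative one — the cascade signature carried by the line
shape. Excited-state spectra are rescaled to the LS trapezoidal integral on
the evaluation grid: spin changes redistribute emission intensity but do
not create it, so transients integrate to zero.

For kinetic traces, the generator produces population-weighted observables
$w_{IS}N_{IS} + w_{HS}N_{HS}$. `weights_from_amplitudes()` inverts the
algebraic map between state weights and biexponential amplitudes, so a
published amplitude pair $(a_1, a_3)$ can be reproduced exactly by the
cascade generator — that is how the recovery experiments regenerate the
published table rows. The XANES observable cannot distinguish the two domed
states; its default weights are equal.

What the generator does *not* model: detector response, the
elastic-scatter background under Kβ, shot-to-shot jitter, pump–probe
time-zero drift, photoreduction chemistry, or a physical multiplet
calculation of the line shapes (the width-vs-spin law is an empirical
linear proxy). Passing recovery tests on these synthetics therefore
demonstrates the *inference machinery* — not that real data are this
well-behaved. The packaged reference library for spin matching is likewise
generated from the same synthetic species models (clearly a toy; users load
their own measured references for real assignments).

# Yield accounting

`excited_fraction()` uses the depth-averaged decadic Beer–Lambert form
$f = \Phi\,(1-10^{-A})/N$ with $\Phi$ the photon areal density, $A$ the
absorbance and $N$ the molecular areal density — not the front-surface
approximation, which errs at the $A \sim 1$ optical densities of a
millimolar heme solution in a ~100 µm jet. Saturation ($f > 1$) is capped
with a warning. The observed counterpart scales a 100%-conversion reference
transient onto the measurement; the two estimates are declared consistent
when they agree within a factor of 2. Pump scattering and reflection losses
are not modelled. The absorptivity at the pump wavelength and the jet
thickness are config placeholders (the demo uses 5 mJ/cm², 50000 /(M cm),
100 µm) to be overridden with instrument values.

# Numerical choices

* Interpolation is linear everywhere in I/O; target grids must lie inside
  the source range (no extrapolation).
* FWHM extraction: bisection to 1e-9 eV after a 1e-10-tolerance maximum
  search; profiles without two half-max crossings are an error.
* Kinetic fits: `nls.lm` with `ftol = ptol = 1e-12`, log-parameters clamped
  to ±25 to keep `exp()` finite; non-finite model values are pushed back by
  a large constant residual; non-convergence is returned flagged, never
  silently.
* The species-model width calibration solves (by `uniroot`, 1e-10) for the
  nominal width that makes the *numeric* FWHM excess equal the requested
  broadening under each state's asymmetry.
* Degenerate inputs are rejected with specific messages: descending grids
  (naming the offending rows), flat spectra, all-zero transients, disjoint
  grids, zero reference spectra, non-positive excitation conditions.
* All stochastic outputs take explicit integer seeds; identical seeds give
  bit-identical results.

# Validation problem sizes

The shipped validation uses ensembles sized for laptop-scale runs: 200
replicate traces per table-row recovery experiment, 300 simulations for
bootstrap-coverage calibration (100 bootstrap replicates each), 100
simulations for the model-comparison and shift-recovery checks, 500 for the
noise-model check, spectra on 201-point grids and traces on 71-point delay
grids. Medians over 200 replicates determine recovered constants to well
within the published uncertainties of the corresponding quantities.

# Limitations

The pipeline fits single-energy or single-width kinetic traces, as the
underlying analysis does: there is no global (wavelength-resolved) lifetime
or target analysis, no decomposition of the transient matrix, and no
quantitative spin-population unmixing from Kβ shapes (the fingerprints are
deliberately reported with an ambiguity caveat). XANES is treated as a
scalar amplitude at the kinetics energy, not a simulated edge. Energy
calibration, detector-image reduction and facility file formats are out of
scope; the I/O layer reads columnar text.
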