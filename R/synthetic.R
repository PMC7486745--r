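#' Spin states of the ferric heme iron
#'
#' The three states of the relaxation cascade: low spin (LS, S = 1/2,
#' 1 unpaired 3d electron, the ground state), intermediate spin (IS,
#' S = 3/2, 3 unpaired) and high spin (HS, S = 5/2, 5 unpaired).
#'
#' @param name One of \code{"LS"}, \code{"IS"}, \code{"HS"}.
#' @return List with \code{name}, \code{two_S} (twice the spin quantum
#'   number) and \code{n_unpaired}, class \code{spin_state}.
#' @export
spin_state <- function(name = c("LS", "IS", "HS")) {
  name <- match.arg(name)
  n <- c(LS = 1L, IS = 3L, HS = 5L)[[name]]
  structure(list(name = name, two_S = n, n_unpaired = n),
            class = "spin_state")
}

#' Per-spin-state emission line model
#'
#' Parameterizes how the Fe K-alpha and K-beta emission profiles of the
#' three spin states differ:
#' \itemize{
#' \item K-alpha: a doublet of asymmetric pseudo-Voigt lines at the
#'   canonical 6404 (K-alpha-1) and 6391 eV (K-alpha-2) centers with a 2:1
#'   peak-amplitude ratio. The K-alpha-1 width grows linearly with the
#'   number of unpaired 3d electrons up to saturation at n = 3:
#'   \eqn{\Delta\mathrm{FWHM}(n) = \beta (n-1)/2} for \eqn{n \le 3},
#'   constant beyond, with \eqn{\beta} calibrated at construction so the
#'   measured (numeric) high-spin minus low-spin K-alpha-1 FWHM difference
#'   equals \code{kalpha_broadening_ev} exactly.
#' \item K-beta: mainline at 7058 eV and low-energy satellite at 7043 eV;
#'   with increasing spin a fraction of the mainline amplitude per spin step
#'   is transferred to the satellite and the mainline shifts to the blue.
#'   Only the sign pattern is physically anchored; the magnitudes are free
#'   parameters.
#' }
#'
#' @param kalpha_centers K-alpha-1/K-alpha-2 centers (eV).
#' @param kalpha_fwhm_ls_ev Low-spin K-alpha-1 nominal FWHM (eV).
#' @param kalpha_eta Lorentzian mixing fraction of the K-alpha lines.
#' @param kalpha_asym Low-spin asymmetry rate (1/eV); positive skews the
#'   line toward the blue wing.
#' @param kalpha_asym_step Asymmetry-rate increment per spin step (not
#'   saturating): the excess width of the excited states sits predominantly
#'   on the blue wing, which is what places the positive transient lobe
#'   ~2 eV above the line center, and the high-spin state is slightly more
#'   blue-weighted than the intermediate one even though their total FWHM
#'   excess is equal, so the positive lobe carries relatively more
#'   high-spin signal.
#' @param kalpha_broadening_ev High-spin minus low-spin K-alpha-1 numeric
#'   FWHM difference (eV) the model is calibrated to.
#' @param kalpha_amp_ratio K-alpha-2 : K-alpha-1 peak-amplitude ratio.
#' @param kbeta_centers Mainline/satellite centers (eV).
#' @param kbeta_fwhm_ev Mainline and satellite FWHM (eV).
#' @param kbeta_eta Lorentzian mixing of the K-beta lines.
#' @param kbeta_side_amp_ls Low-spin satellite amplitude relative to the
#'   mainline.
#' @param kbeta_transfer_per_step Mainline amplitude fraction transferred to
#'   the satellite per spin step (n increasing by 2).
#' @param kbeta_shift_per_step_ev Mainline blue shift per spin step (eV).
#' @return Object of class \code{species_line_model} carrying the per-state
#'   [apv_params]; K-alpha widths are pre-calibrated as described.
#' @export
species_line_model <- function(kalpha_centers = c(6404, 6391),
                               kalpha_fwhm_ls_ev = 2.2,
                               kalpha_eta = 0.5,
                               kalpha_asym = 0.1,
                               kalpha_asym_step = 0.15,
                               kalpha_broadening_ev = 0.7,
                               kalpha_amp_ratio = 0.5,
                               kbeta_centers = c(7058, 7043),
                               kbeta_fwhm_ev = c(3.2, 4.5),
                               kbeta_eta = 0.5,
                               kbeta_side_amp_ls = 0.12,
                               kbeta_transfer_per_step = 0.10,
                               kbeta_shift_per_step_ev = 0.3) {
  stopifnot(kalpha_centers[1L] > kalpha_centers[2L],
            kalpha_fwhm_ls_ev > 0, kalpha_broadening_ev >= 0,
            kbeta_centers[1L] > kbeta_centers[2L])
  ls1 <- apv_params(1, kalpha_centers[1L], kalpha_fwhm_ls_ev,
                    eta = kalpha_eta, asym = kalpha_asym)
  fwhm_ls <- numeric_fwhm(ls1)
  # FWHM excess is linear in n with saturation at n = 3 (LS 0, IS = HS);
  # the asymmetry rate keeps growing with the spin step
  excess <- c(LS = 0, IS = kalpha_broadening_ev, HS = kalpha_broadening_ev)
  asym_by_state <- kalpha_asym + kalpha_asym_step * c(LS = 0, IS = 1, HS = 2)
  # calibrate the nominal-width parameter per state so the *measured*
  # (numeric) FWHM excess over the low-spin line equals the requested
  # broadening under that state's asymmetry
  fwhm0_for_excess <- function(target, asym) {
    if (target <= 0) return(kalpha_fwhm_ls_ev)
    stats::uniroot(function(f0) {
      p <- apv_params(1, kalpha_centers[1L], f0, eta = kalpha_eta,
                      asym = asym)
      numeric_fwhm(p) - fwhm_ls - target
    }, lower = 0.2 * kalpha_fwhm_ls_ev,
       upper = kalpha_fwhm_ls_ev + 4 * target + 1, tol = 1e-10)$root
  }
  kalpha_fwhm0 <- mapply(fwhm0_for_excess, excess, asym_by_state)
  structure(list(
    kalpha_centers = kalpha_centers, kalpha_fwhm0 = kalpha_fwhm0,
    kalpha_eta = kalpha_eta, kalpha_asym = asym_by_state,
    kalpha_amp_ratio = kalpha_amp_ratio,
    kalpha_broadening_ev = kalpha_broadening_ev,
    kbeta_centers = kbeta_centers, kbeta_fwhm_ev = kbeta_fwhm_ev,
    kbeta_eta = kbeta_eta, kbeta_side_amp_ls = kbeta_side_amp_ls,
    kbeta_transfer_per_step = kbeta_transfer_per_step,
    kbeta_shift_per_step_ev = kbeta_shift_per_step_ev),
    class = "species_line_model")
}

# spin step index: LS 0, IS 1, HS 2
spin_step <- function(state) (state$n_unpaired - 1L) / 2L

#' Per-state K-alpha doublet parameters
#'
#' @param state A [spin_state] (or its name).
#' @param model A [species_line_model].
#' @return An [apv_doublet] for that state (unit K-alpha-1 amplitude).
#' @export
species_doublet <- function(state, model = species_line_model()) {
  if (is.character(state)) state <- spin_state(state)
  f0 <- model$kalpha_fwhm0[[state$name]]
  asym <- model$kalpha_asym[[state$name]]
  apv_doublet(
    apv_params(1, model$kalpha_centers[1L], f0,
               eta = model$kalpha_eta, asym = asym),
    apv_params(model$kalpha_amp_ratio, model$kalpha_centers[2L], f0,
               eta = model$kalpha_eta, asym = asym),
    baseline = 0)
}

#' Noiseless emission spectrum of one spin state
#'
#' Sum of asymmetric pseudo-Voigt lines at the model's centers for the
#' requested channel and state. Spectra of the excited states are rescaled
#' so their trapezoidal integral over the supplied grid equals the low-spin
#' one: spin changes redistribute emission intensity across the line but do
#' not create or destroy it, so transients constructed from these spectra
#' integrate to zero over the grid.
#'
#' @param channel \code{"kalpha"} or \code{"kbeta"}.
#' @param state A [spin_state] or its name.
#' @param grid Energy grid (eV) covering all line centers +- 5 FWHM.
#' @param model A [species_line_model].
#' @return An [energy_spectrum] (laser state \code{"na"}).
#' @export
species_spectrum <- function(channel = c("kalpha", "kbeta"), state,
                             grid = NULL, model = species_line_model()) {
  channel <- match.arg(channel)
  if (is.character(state)) state <- spin_state(state)
  stopifnot(inherits(state, "spin_state"))
  if (is.null(grid)) grid <- default_grid(channel)
  raw <- function(st) {
    if (channel == "kalpha") {
      doublet_profile(grid, species_doublet(st, model))
    } else {
      step <- spin_step(st)
      amp_main <- 1 - model$kbeta_transfer_per_step * step
      amp_side <- model$kbeta_side_amp_ls +
        model$kbeta_transfer_per_step * step
      c_main <- model$kbeta_centers[1L] + model$kbeta_shift_per_step_ev * step
      apv_profile(grid, apv_params(amp_main, c_main, model$kbeta_fwhm_ev[1L],
                                   eta = model$kbeta_eta)) +
        apv_profile(grid, apv_params(amp_side, model$kbeta_centers[2L],
                                     model$kbeta_fwhm_ev[2L],
                                     eta = model$kbeta_eta))
    }
  }
  check_grid_coverage(channel, grid, model)
  y <- raw(state)
  if (state$name != "LS") {
    y <- y * trapz_int(grid, raw(spin_state("LS"))) / trapz_int(grid, y)
  }
  energy_spectrum(grid, y, channel = channel)
}

check_grid_coverage <- function(channel, grid, model) {
  if (channel == "kalpha") {
    centers <- model$kalpha_centers
    w <- max(model$kalpha_fwhm0)
  } else {
    centers <- model$kbeta_centers
    w <- max(model$kbeta_fwhm_ev)
  }
  if (min(grid) > min(centers) - 2 * w || max(grid) < max(centers) + 2 * w) {
    stop("grid must cover all line centers +- 2 FWHM", call. = FALSE)
  }
  invisible(TRUE)
}

trapz_int <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L])) / 2

#' Default energy grids
#'
#' 0.2 eV spacing over 6380-6420 eV (K-alpha) or 7020-7080 eV (K-beta).
#'
#' @param channel \code{"kalpha"} or \code{"kbeta"}.
#' @param step_ev Grid spacing (eV).
#' @return Numeric energy grid.
#' @export
default_grid <- function(channel = c("kalpha", "kbeta"), step_ev = 0.2) {
  channel <- match.arg(channel)
  if (channel == "kalpha") seq(6380, 6420, by = step_ev)
  else seq(7020, 7080, by = step_ev)
}

#' Default pump-probe delay grid
#'
#' Linear coverage of the rise (-1 to 1 ps at 0.05 ps) plus a log-spaced
#' tail out to 50 ps.
#'
#' @param t_max_ps Last delay (ps).
#' @return Ascending delay vector (ps).
#' @export
default_delays <- function(t_max_ps = 50) {
  sort(unique(c(seq(-1, 1, by = 0.05),
                exp(seq(log(1.1), log(t_max_ps), length.out = 30)))))
}

#' Cascade populations on a delay grid
#'
#' Tabulates the closed-form sequential-cascade populations
#' ([cascade_populations]) per delay.
#'
#' @param params A [cascade_params].
#' @param delays Delays (ps).
#' @return Data frame with columns \code{delay_ps}, \code{n_is},
#'   \code{n_hs}, \code{n_gs}, \code{pumped}.
#' @export
simulate_populations <- function(params, delays = default_delays()) {
  pop <- cascade_populations(delays, params)
  data.frame(delay_ps = delays, n_is = pop$n_is, n_hs = pop$n_hs,
             n_gs = pop$n_gs, pumped = pop$pumped)
}

#' Synthetic laser-off / laser-on spectrum pairs along a delay scan
#'
#' For each delay, the laser-on spectrum is the population-weighted mixture
#' \deqn{(1 - N_{IS} - N_{HS})\,S_{LS} + N_{IS}\,S_{IS} + N_{HS}\,S_{HS}}
#' of the species spectra plus counting-like heteroscedastic Gaussian noise
#' with \eqn{\sigma(E) = \mathrm{noise}\cdot S_{max}\sqrt{S(E)/S_{max}}};
#' the laser-off spectrum is the low-spin spectrum with independent noise of
#' the same model. Reproducible under a fixed seed.
#'
#' @param channel \code{"kalpha"} or \code{"kbeta"}.
#' @param params A [cascade_params].
#' @param delays Delays (ps).
#' @param noise_level Relative 1-sigma noise at the spectrum peak (>= 0);
#'   0 gives noiseless spectra (no \code{sigma} field).
#' @param seed Integer seed.
#' @param grid Energy grid; defaults to [default_grid].
#' @param model A [species_line_model].
#' @return List with one element per delay: \code{delay_ps}, \code{off},
#'   \code{on} ([energy_spectrum]s).
#' @export
synth_timeseries <- function(channel = c("kalpha", "kbeta"), params,
                             delays = default_delays(), noise_level = 0.02,
                             seed = 1, grid = NULL,
                             model = species_line_model()) {
  channel <- match.arg(channel)
  stopifnot(inherits(params, "cascade_params"))
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  if (is.null(grid)) grid <- default_grid(channel)
  s_ls <- species_spectrum(channel, "LS", grid, model)$intensity
  s_is <- species_spectrum(channel, "IS", grid, model)$intensity
  s_hs <- species_spectrum(channel, "HS", grid, model)$intensity
  pop <- cascade_populations(delays, params)
  set.seed(seed)
  noisy <- function(y, state, delay) {
    if (noise_level == 0) {
      return(energy_spectrum(grid, y, channel = channel, laser_state = state,
                             delay_ps = delay))
    }
    sd_e <- noise_level * max(y) * sqrt(pmax(y, 0) / max(y))
    energy_spectrum(grid, y + stats::rnorm(length(y), sd = sd_e),
                    sigma = pmax(sd_e, 1e-12 * max(y)),
                    channel = channel, laser_state = state, delay_ps = delay)
  }
  lapply(seq_along(delays), function(i) {
    on_clean <- (1 - pop$n_is[i] - pop$n_hs[i]) * s_ls +
      pop$n_is[i] * s_is + pop$n_hs[i] * s_hs
    list(delay_ps = delays[i],
         off = noisy(s_ls, "off", delays[i]),
         on = noisy(on_clean, "on", delays[i]))
  })
}

#' Synthetic kinetic trace of a population-weighted observable
#'
#' \deqn{y(t) = w_{IS}\,N_{IS}(t) + w_{HS}\,N_{HS}(t) + \epsilon}
#' with homoscedastic Gaussian noise of standard deviation
#' \code{noise_level} times the peak of the clean trace. For
#' \code{kind = "kalpha_fwhm"} the default weights are the per-state
#' K-alpha-1 FWHM increments over low spin, so the trace is the model
#' K-alpha-1 FWHM excess in eV; for \code{kind = "xanes_amplitude"} both
#' doming states contribute with equal unit weight by default (the two are
#' not distinguishable in the edge transient).
#'
#' @param kind \code{"xanes_amplitude"} or \code{"kalpha_fwhm"}.
#' @param params A [cascade_params].
#' @param weights Length-2 numeric \code{(w_IS, w_HS)}; \code{NULL} for the
#'   kind's default.
#' @param delays Delays (ps).
#' @param noise_level Relative 1-sigma noise at the trace peak (>= 0).
#' @param seed Integer seed.
#' @param model A [species_line_model] (for the FWHM weights).
#' @return A [kinetic_trace]; \code{sigma} is the (known) noise level, or
#'   absent when \code{noise_level = 0}.
#' @export
synth_kinetic_trace <- function(kind = c("xanes_amplitude", "kalpha_fwhm"),
                                params, weights = NULL,
                                delays = default_delays(),
                                noise_level = 0.05, seed = 1,
                                model = species_line_model()) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "cascade_params"))
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  if (is.null(weights)) {
    weights <- if (kind == "kalpha_fwhm") {
      rep(model$kalpha_broadening_ev, 2L)
    } else c(1, 1)
  }
  s <- params$irf_fwhm_ps / (2 * sqrt(2 * log(2)))
  if (min(delays) > params$t0_ps - 3 * s || max(delays) < params$t0_ps + 3 * s) {
    warning("delay grid does not cover t0 +- 3 IRF widths; ",
            "the rise will be ill-constrained in fits")
  }
  pop <- cascade_populations(delays, params)
  clean <- weights[1L] * pop$n_is + weights[2L] * pop$n_hs
  label <- if (kind == "kalpha_fwhm") "Kalpha1 FWHM" else "XANES@7125.3eV"
  if (noise_level == 0) {
    return(kinetic_trace(delays, clean, label = label))
  }
  set.seed(seed)
  sd0 <- noise_level * max(abs(clean))
  kinetic_trace(delays, clean + stats::rnorm(length(delays), sd = sd0),
                sigma = rep(sd0, length(delays)), label = label)
}

#' Cascade observable weights reproducing given biexponential amplitudes
#'
#' The population-weighted observable
#' \eqn{w_{IS} N_{IS} + w_{HS} N_{HS}} is algebraically a biexponential
#' \eqn{a_1 H(t;\tau_1) + a_3 H(t;\tau_3)}. This inverts that map: given the
#' target amplitudes \eqn{(a_1, a_3)} (e.g. a published fit table row) it
#' returns the \eqn{(w_{IS}, w_{HS})} that generate them:
#' \deqn{w_{HS} = \frac{a_3(\tau_3 - \tau_1)}{f\,\tau_3}, \qquad
#'   w_{IS} = \frac{a_1 + a_3}{f}.}
#'
#' @param a1,a3 Amplitudes of the fast/slow components.
#' @param params A [cascade_params].
#' @return Length-2 numeric \code{(w_IS, w_HS)}.
#' @export
weights_from_amplitudes <- function(a1, a3, params) {
  stopifnot(inherits(params, "cascade_params"))
  f <- params$f_exc
  c(w_is = (a1 + a3) / f,
    w_hs = a3 * (params$tau3_ps - params$tau1_ps) / (f * params$tau3_ps))
}
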