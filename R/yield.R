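#' Pump excitation conditions
#'
#' @param fluence_mj_cm2 Pump fluence (mJ/cm^2).
#' @param wavelength_nm Pump wavelength (nm).
#' @param conc_mM Chromophore concentration (mmol/L).
#' @param path_um Sample (jet) thickness (micrometres).
#' @param eps_M_cm Decadic molar absorptivity at the pump wavelength
#'   (1/(M cm)).
#' @return Object of class \code{excitation_conditions}.
#' @export
excitation_conditions <- function(fluence_mj_cm2, wavelength_nm, conc_mM,
                                  path_um, eps_M_cm) {
  vals <- c(fluence_mj_cm2, wavelength_nm, conc_mM, path_um, eps_M_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all excitation conditions must be strictly positive", call. = FALSE)
  }
  structure(list(fluence_mj_cm2 = fluence_mj_cm2,
                 wavelength_nm = wavelength_nm, conc_mM = conc_mM,
                 path_um = path_um, eps_M_cm = eps_M_cm),
            class = "excitation_conditions")
}

#' Expected photoexcited fraction from Beer-Lambert absorption
#'
#' Depth-averaged decadic Beer-Lambert estimate (not the front-surface
#' approximation, which errs when the optical density approaches 1): with
#' photon areal density \eqn{\Phi = F/E_{photon}}, absorbance
#' \eqn{A = \epsilon c \ell} and molecular areal density
#' \eqn{N = c\,\ell\,N_A},
#' \deqn{f = \frac{\Phi\,(1 - 10^{-A})}{N},}
#' capped at 1 (with a warning) in the saturation regime. One absorbed
#' photon is assumed to excite one chromophore; pump scattering and
#' reflection losses are not modelled.
#'
#' @param c An [excitation_conditions].
#' @return Excited molecular fraction in (0, 1].
#' @export
excited_fraction <- function(c) {
  stopifnot(inherits(c, "excitation_conditions"))
  h <- 6.62607015e-34   # J s
  cl <- 2.99792458e8    # m/s
  na <- 6.02214076e23   # 1/mol
  e_photon <- h * cl / (c$wavelength_nm * 1e-9)          # J
  phi <- (c$fluence_mj_cm2 * 1e-3) / e_photon            # photons / cm^2
  conc_m <- c$conc_mM * 1e-3                             # mol / L
  path_cm <- c$path_um * 1e-4
  a_od <- c$eps_M_cm * conc_m * path_cm
  n_area <- conc_m * 1e-3 * path_cm * na                 # molecules / cm^2
  f <- phi * (1 - 10^(-a_od)) / n_area
  if (f > 1) {
    warning("estimated excitation saturates (> 1 photon absorbed per ",
            "molecule); capping the fraction at 1")
    f <- 1
  }
  f
}

#' Observed excited fraction from a transient amplitude
#'
#' Least-squares amplitude scale of a 100%-conversion reference difference
#' spectrum onto the measured transient; the scale is the excited fraction.
#' A poor shape match (relative residual above \code{mismatch_tol}) is
#' flagged: the scale is then not interpretable as a population.
#'
#' @param transient A [transient_spectrum].
#' @param full_conversion_reference A [transient_spectrum]: the difference
#'   expected at complete conversion (e.g. from the synthetic generator with
#'   \code{f_exc = 1}), on a grid overlapping the transient's.
#' @param mismatch_tol Relative residual RMS (to the reference RMS x scale)
#'   above which the shape-mismatch flag is set.
#' @return List with \code{fraction}, \code{residual_rms},
#'   \code{mismatch} (logical).
#' @export
observed_fraction <- function(transient, full_conversion_reference,
                              mismatch_tol = 0.5) {
  validate_transient_spectrum(transient)
  validate_transient_spectrum(full_conversion_reference)
  ref <- full_conversion_reference
  if (max(abs(ref$delta)) == 0) {
    stop("reference transient is identically zero", call. = FALSE)
  }
  lo <- max(min(transient$energy_ev), min(ref$energy_ev))
  hi <- min(max(transient$energy_ev), max(ref$energy_ev))
  if (lo >= hi) stop("grids do not overlap", call. = FALSE)
  keep <- transient$energy_ev >= lo & transient$energy_ev <= hi
  tv <- transient$delta[keep]
  rv <- stats::approx(ref$energy_ev, ref$delta,
                      xout = transient$energy_ev[keep])$y
  scale <- sum(tv * rv) / sum(rv^2)
  res <- sqrt(mean((tv - scale * rv)^2))
  ref_rms <- sqrt(mean(rv^2))
  mismatch <- res > mismatch_tol * abs(scale) * ref_rms
  list(fraction = scale, residual_rms = res, mismatch = mismatch)
}

#' Consistency of expected and observed excitation fractions
#'
#' The two independent yield estimates (Beer-Lambert expectation vs
#' transient-amplitude observation) are deemed consistent when they agree to
#' within a factor of 2.
#'
#' @param f_expected,f_observed Fractions in (0, 1].
#' @return List with \code{ratio} (>= 1), \code{agree}
#'   (\code{ratio <= 2}), \code{f_expected}, \code{f_observed}.
#' @export
consistency_ratio <- function(f_expected, f_observed) {
  if (!is.finite(f_expected) || !is.finite(f_observed) ||
      f_expected <= 0 || f_observed <= 0 ||
      f_expected > 1 || f_observed > 1) {
    stop("fractions must be in (0, 1]", call. = FALSE)
  }
  ratio <- max(f_expected, f_observed) / min(f_expected, f_observed)
  list(ratio = ratio, agree = ratio <= 2,
       f_expected = f_expected, f_observed = f_observed)
}
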