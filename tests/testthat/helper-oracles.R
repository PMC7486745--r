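# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms: quadrature instead of the EMG expression,
# Runge-Kutta instead of the cascade solution, dense grid scans instead of
# bisection.

# Gaussian-IRF x causal-exponential convolution by adaptive quadrature
quad_conv <- function(t, t0, irf_fwhm, tau) {
  s <- irf_fwhm / (2 * sqrt(2 * log(2)))
  vapply(t, function(tt) {
    if (tt <= t0 - 10 * s) return(0)
    stats::integrate(function(x) {
      stats::dnorm(x, mean = t0, sd = s) * exp(-(tt - x) / tau)
    }, lower = t0 - 10 * s, upper = min(tt, t0 + 10 * s),
    rel.tol = 1e-12, abs.tol = 1e-14, subdivisions = 1000L)$value
  }, 1)
}

# cascade populations by explicit Runge-Kutta integration of the rate
# equations with a Gaussian source term
ode_populations <- function(delays, p) {
  s <- p$irf_fwhm_ps / (2 * sqrt(2 * log(2)))
  rhs <- function(t, y, parms) {
    list(c(p$f_exc * stats::dnorm(t, p$t0_ps, s) - y[1] / p$tau1_ps,
           y[1] / p$tau1_ps - y[2] / p$tau3_ps,
           y[2] / p$tau3_ps))
  }
  t_start <- min(c(delays, p$t0_ps - 8 * s))
  tt <- sort(unique(c(t_start, delays)))
  out <- deSolve::ode(c(0, 0, 0), tt, rhs, NULL, method = "ode45",
                      atol = 1e-12, rtol = 1e-10)
  idx <- match(delays, out[, 1])
  list(n_is = out[idx, 2], n_hs = out[idx, 3], recovered = out[idx, 4])
}

# FWHM by brute-force scan of a densely sampled profile with linear
# interpolation of the half-max crossings
scan_fwhm <- function(p, step = 1e-4) {
  w <- 10 * p$fwhm0_ev
  e <- seq(p$center_ev - w, p$center_ev + w, by = step)
  y <- apv_profile(e, p)
  imax <- which.max(y)
  half <- y[imax] / 2
  li <- max(which(y[1:imax] <= half))
  ri <- imax + min(which(y[imax:length(y)] <= half)) - 1L
  xl <- stats::approx(y[c(li, li + 1L)], e[c(li, li + 1L)], xout = half)$y
  xr <- stats::approx(y[c(ri - 1L, ri)], e[c(ri - 1L, ri)], xout = half)$y
  xr - xl
}

# piecewise-linear interpolation written out longhand
pl_interp <- function(x, y, xout) {
  vapply(xout, function(x0) {
    i <- findInterval(x0, x)
    if (x0 == x[i]) return(y[i])
    y[i] + (y[i + 1L] - y[i]) * (x0 - x[i]) / (x[i + 1L] - x[i])
  }, 1)
}

# Table-1-style ground truths used by generator round trips
xanes_truth <- list(irf = 0.14, tau1 = 0.61, a1 = 0.70, tau3 = 8.7, a3 = 0.30)
xes_truth <- list(irf = 0.15, tau1 = 0.63, a1 = 0.50, tau3 = 7.8, a3 = 0.50)

make_table_trace <- function(truth, seed, noise = 0.05, f_exc = 1) {
  p <- cascade_params(0, truth$irf, truth$tau1, truth$tau3, f_exc)
  w <- weights_from_amplitudes(truth$a1, truth$a3, p)
  synth_kinetic_trace("xanes_amplitude", p, weights = w,
                      noise_level = noise, seed = seed)
}
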