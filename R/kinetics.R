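#' Gaussian-IRF-convolved exponential decay (exponentially modified Gaussian)
#'
#' Closed form for the convolution of a unit-area Gaussian instrument
#' response of FWHM \code{irf_fwhm} with a causal exponential decay
#' \eqn{e^{-(t-t_0)/\tau}\,\theta(t-t_0)}:
#' \deqn{H(t) = \tfrac12 \exp\!\left(\frac{\sigma^2}{2\tau^2} -
#'   \frac{t-t_0}{\tau}\right)\,
#'   \mathrm{erfc}\!\left(\frac{\sigma/\tau - (t-t_0)/\sigma}{\sqrt2}\right)}
#' with \eqn{\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})}. Evaluated in an
#' overflow-safe form via the scaled complementary error function, so it is
#' stable for any \eqn{\sigma/\tau} ratio.
#'
#' @param t Times (ps).
#' @param t0 Time zero (ps).
#' @param irf_fwhm Gaussian IRF full width at half maximum (ps), > 0.
#' @param tau Decay constant (ps), > 0.
#' @return \eqn{H(t)}, same length as \code{t}; rises from 0 through the IRF
#'   and decays with \code{tau}, peak amplitude < 1.
#' @export
emg_response <- function(t, t0, irf_fwhm, tau) {
  stopifnot(tau > 0, irf_fwhm > 0)
  s <- irf_fwhm / (2 * sqrt(2 * log(2)))
  u <- (t - t0) / s
  r <- s / tau
  z <- (r - u) / sqrt(2)
  out <- numeric(length(t))
  neg <- z < 0
  # z >= 0: erfc underflows; use erfcx with the exactly cancelling exponent
  if (any(!neg)) {
    out[!neg] <- 0.5 * erfcx_safe(z[!neg]) * exp(-u[!neg]^2 / 2)
  }
  # z < 0: erfc in (1, 2), the plain form is safe (exponent is negative)
  if (any(neg)) {
    out[neg] <- 0.5 * exp(r^2 / 2 - u[neg] * r) * pracma::erfc(z[neg])
  }
  out
}

# scaled complementary error function with an asymptotic branch: pracma's
# rational approximation overflows to NaN for z >~ 27
erfcx_safe <- function(z) {
  out <- numeric(length(z))
  big <- z > 20
  if (any(big)) {
    zb <- z[big]
    out[big] <- (1 - 1 / (2 * zb^2) + 3 / (4 * zb^4) - 15 / (8 * zb^6)) /
      (zb * sqrt(pi))
  }
  out[!big] <- pracma::erfcx(z[!big])
  out
}

#' Sequential cascade parameters
#'
#' Parameters of the two-step relaxation cascade
#' ground \eqn{\to} intermediate-spin \eqn{\to} high-spin \eqn{\to} ground:
#' a Gaussian pump of total excited fraction \code{f_exc} promptly populates
#' the intermediate-spin state, which decays to the high-spin state with
#' \code{tau1_ps}; the high-spin state returns to the ground state with
#' \code{tau3_ps}.
#'
#' @param t0_ps Time zero (ps).
#' @param irf_fwhm_ps Gaussian IRF FWHM (ps), > 0.
#' @param tau1_ps Intermediate-to-high-spin decay constant (ps), > 0.
#' @param tau3_ps High-spin-to-ground decay constant (ps), > 0.
#' @param f_exc Initially excited molecular fraction, in (0, 1].
#' @return An object of class \code{cascade_params}.
#' @export
cascade_params <- function(t0_ps = 0, irf_fwhm_ps = 0.14, tau1_ps = 0.61,
                           tau3_ps = 8.7, f_exc = 0.3) {
  if (irf_fwhm_ps <= 0) stop("irf_fwhm_ps must be > 0", call. = FALSE)
  if (tau1_ps <= 0 || tau3_ps <= 0) stop("time constants must be > 0", call. = FALSE)
  if (f_exc <= 0 || f_exc > 1) stop("f_exc must be in (0, 1]", call. = FALSE)
  structure(list(t0_ps = t0_ps, irf_fwhm_ps = irf_fwhm_ps, tau1_ps = tau1_ps,
                 tau3_ps = tau3_ps, f_exc = f_exc),
            class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat(sprintf(
    "<cascade_params> t0 %.3g ps, IRF %.3g ps, tau1 %.3g ps, tau3 %.3g ps, f_exc %.3g\n",
    x$t0_ps, x$irf_fwhm_ps, x$tau1_ps, x$tau3_ps, x$f_exc))
  invisible(x)
}

#' Closed-form cascade populations under a Gaussian pump
#'
#' Intermediate- and high-spin populations of the sequential scheme, from
#' the IRF-convolved exponential [emg_response] \eqn{H}:
#' \deqn{N_{IS}(t) = f\,H(t;\tau_1), \qquad
#'   N_{HS}(t) = f\,\frac{\tau_3}{\tau_3-\tau_1}\,[H(t;\tau_3) - H(t;\tau_1)].}
#' The degenerate case \eqn{\tau_1 = \tau_3} is evaluated by a symmetric
#' finite-difference limit when the constants differ by less than
#' \code{1e-6} relative.
#'
#' @param t Times (ps).
#' @param p A [cascade_params].
#' @return List with vectors \code{n_is}, \code{n_hs}, \code{n_gs}
#'   (\code{n_gs = 1 - n_is - n_hs}) and \code{pumped}
#'   (= \code{f_exc} times the cumulative Gaussian pump).
#' @export
cascade_populations <- function(t, p) {
  stopifnot(inherits(p, "cascade_params"))
  f <- p$f_exc
  t1 <- p$tau1_ps
  t3 <- p$tau3_ps
  h1 <- emg_response(t, p$t0_ps, p$irf_fwhm_ps, t1)
  n_is <- f * h1
  if (abs(t3 - t1) < 1e-6 * t1) {
    # analytic limit via symmetric finite difference in tau3
    d <- 1e-4 * t1
    hi <- f * ((t1 + d) / d) * (emg_response(t, p$t0_ps, p$irf_fwhm_ps, t1 + d) - h1)
    lo <- f * ((t1 - d) / (-d)) * (emg_response(t, p$t0_ps, p$irf_fwhm_ps, t1 - d) - h1)
    n_hs <- (hi + lo) / 2
  } else {
    h3 <- emg_response(t, p$t0_ps, p$irf_fwhm_ps, t3)
    n_hs <- f * (t3 / (t3 - t1)) * (h3 - h1)
  }
  s <- p$irf_fwhm_ps / (2 * sqrt(2 * log(2)))
  pumped <- f * stats::pnorm(t, mean = p$t0_ps, sd = s)
  list(n_is = n_is, n_hs = n_hs, n_gs = 1 - n_is - n_hs, pumped = pumped)
}

# ---- trace fitting ----------------------------------------------------------

#' Fit an IRF-convolved multiexponential model to a kinetic trace
#'
#' Weighted nonlinear least squares of
#' \deqn{y(t) = b + \sum_i a_i\, H(t;\, t_0, \sigma, \tau_i)}
#' with \eqn{H} the closed-form Gaussian-IRF-convolved exponential
#' ([emg_response]). Weights are \eqn{1/\sigma^2} when the trace carries
#' uncertainties, uniform otherwise. Time constants and the IRF width are
#' optimized in log space so positivity is structural. 68% confidence
#' intervals come from a seeded residual-resampling bootstrap: residuals of
#' the converged fit are resampled with replacement, added back to the fitted
#' curve, and the model is refit; the 16th/84th percentiles of each
#' parameter's bootstrap ensemble are reported.
#'
#' @param trace A [kinetic_trace].
#' @param n_components 1, 2 or 3 exponential components.
#' @param init Optional named list of starting values: \code{t0},
#'   \code{irf_fwhm}, \code{tau} (length \code{n_components}), \code{a}
#'   (same length), \code{baseline}. Missing entries fall back to a data
#'   heuristic.
#' @param fix_irf Optional fixed IRF FWHM (ps); when given, the IRF width is
#'   not a free parameter.
#' @param fit_baseline Logical; fit a constant baseline (default TRUE).
#' @param n_boot Bootstrap replicates for the 68% intervals (default 200);
#'   0 skips the bootstrap (CIs NA).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class \code{biexp_fit}: fitted \code{t0_ps},
#'   \code{irf_fwhm_ps}, \code{components} (data frame \code{a}, \code{tau_ps},
#'   sorted by tau ascending), \code{baseline}, \code{ci68} (per-parameter
#'   68% intervals), \code{residual_rms}, \code{rss}, \code{n},
#'   \code{n_par}, \code{converged}, \code{n_boot}.
#' @export
fit_trace <- function(trace, n_components = 2, init = NULL, fix_irf = NULL,
                      fit_baseline = TRUE, n_boot = 200, seed = 1) {
  validate_kinetic_trace(trace)
  n_components <- as.integer(n_components)
  stopifnot(n_components %in% 1:3)
  t <- trace$delay_ps
  y <- trace$signal
  w <- if (is.null(trace$sigma)) rep(1, length(t)) else 1 / trace$sigma
  init <- trace_init_guess(trace, n_components, init)
  tail_ok <- (max(t) - init$t0) >= 3 * max(init$tau)
  pre_ok <- min(t) <= init$t0 - 2 * init$irf_fwhm
  if (!tail_ok || !pre_ok) {
    warning("trace does not cover pre-rise baseline and >= 3 tau tail; ",
            "time constants may be poorly identifiable")
  }
  free_irf <- is.null(fix_irf)
  irf0 <- if (free_irf) init$irf_fwhm else fix_irf

  pack <- function(t0, irf, tau, a, b) {
    p <- c(t0 = t0)
    if (free_irf) p <- c(p, lirf = log(irf))
    p <- c(p, stats::setNames(log(tau), paste0("ltau", seq_along(tau))),
           stats::setNames(a, paste0("a", seq_along(a))))
    if (fit_baseline) p <- c(p, b = b)
    p
  }
  clamp <- function(x) pmin(pmax(x, -25), 25)  # keep exp() finite, nonzero
  unpack <- function(p) {
    tau <- exp(clamp(unname(p[paste0("ltau", 1:n_components)])))
    list(t0 = unname(p[["t0"]]),
         irf = if (free_irf) exp(clamp(unname(p[["lirf"]]))) else fix_irf,
         tau = tau,
         a = unname(p[paste0("a", 1:n_components)]),
         b = if (fit_baseline) unname(p[["b"]]) else 0)
  }
  model <- function(p, tt) {
    q <- unpack(p)
    m <- q$b
    for (i in seq_len(n_components)) {
      m <- m + q$a[i] * emg_response(tt, q$t0, q$irf, q$tau[i])
    }
    m
  }
  do_fit <- function(yy, par0) {
    minpack.lm::nls.lm(par = par0, fn = function(p) {
      r <- w * (yy - model(p, t))
      if (any(!is.finite(r))) r[] <- 1e6  # push the optimizer back
      r
    }, control = minpack.lm::nls.lm.control(
      maxiter = 300, maxfev = 3000, ftol = 1e-12, ptol = 1e-12))
  }
  par0 <- pack(init$t0, irf0, init$tau, init$a, init$baseline)
  fit <- do_fit(y, par0)
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("kinetic fit did not converge (info = ", fit$info, "): ",
            fit$message)
  }
  q <- unpack(fit$par)
  yhat <- model(fit$par, t)
  res <- y - yhat

  # linearized parameter sigmas from the Gauss-Newton covariance; the log
  # parameters are mapped back by the delta method
  dof <- max(length(t) - length(fit$par), 1L)
  s2 <- sum(fit$fvec^2) / dof
  # invert J'J by SVD with the small singular values floored: directions the
  # data do not constrain then get large (not NaN, not falsely small) sigmas
  sv <- svd(fit$hessian)
  d <- pmax(sv$d, 1e-12 * max(sv$d, .Machine$double.eps))
  hinv <- sv$v %*% (t(sv$u) / d)
  par_sigma <- sqrt(pmax(diag(s2 * hinv), 0))
  names(par_sigma) <- names(fit$par)
  a_sigma <- unname(par_sigma[paste0("a", 1:n_components)])
  tau_sigma <- unname(par_sigma[paste0("ltau", 1:n_components)]) * q$tau

  ci68 <- NULL
  boot_pars <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    boot_pars <- matrix(NA_real_, n_boot, length(fit$par),
                        dimnames = list(NULL, names(fit$par)))
    for (b in seq_len(n_boot)) {
      yb <- yhat + sample(res, length(res), replace = TRUE)
      fb <- try(do_fit(yb, fit$par), silent = TRUE)
      if (!inherits(fb, "try-error") && fb$info %in% 1:4) {
        boot_pars[b, ] <- fb$par
      }
    }
    nat <- natural_params(boot_pars, n_components, free_irf, fix_irf,
                          fit_baseline)
    ci68 <- apply(nat, 2, stats::quantile, probs = c(0.16, 0.84),
                  na.rm = TRUE)
  }

  ord <- order(q$tau)
  comps <- data.frame(a = q$a[ord], tau_ps = q$tau[ord],
                      a_sigma = a_sigma[ord], tau_sigma = tau_sigma[ord])
  rt <- comps$tau_ps[-1] / comps$tau_ps[-nrow(comps)]
  structure(list(t0_ps = q$t0, irf_fwhm_ps = q$irf, components = comps,
                 collinear_taus = any(rt < 2),
                 baseline = q$b, ci68 = ci68,
                 residual_rms = sqrt(mean(res^2)),
                 rss = sum((w * res)^2), n = length(t),
                 n_par = length(fit$par), converged = converged,
                 n_boot = n_boot, order = ord, fitted = yhat,
                 residuals = res, label = trace$label),
            class = "biexp_fit")
}

# map packed optimizer parameters to natural units, components tau-sorted
natural_params <- function(mat, n_components, free_irf, fix_irf, fit_baseline) {
  out <- matrix(NA_real_, nrow(mat), 2 + 2 * n_components + 1,
                dimnames = list(NULL, c("t0_ps", "irf_fwhm_ps",
                                        paste0("tau", 1:n_components, "_ps"),
                                        paste0("a", 1:n_components),
                                        "baseline")))
  for (i in seq_len(nrow(mat))) {
    p <- mat[i, ]
    if (anyNA(p)) next
    tau <- exp(pmin(pmax(p[paste0("ltau", 1:n_components)], -25), 25))
    a <- p[paste0("a", 1:n_components)]
    ord <- order(tau)
    out[i, ] <- c(p[["t0"]],
                  if (free_irf) exp(p[["lirf"]]) else fix_irf,
                  tau[ord], a[ord],
                  if (fit_baseline) p[["b"]] else 0)
  }
  out
}

# heuristic starting values from the trace itself
trace_init_guess <- function(trace, n_components, init = NULL) {
  t <- trace$delay_ps
  y <- trace$signal
  base0 <- stats::median(y[t <= stats::quantile(t, 0.1)])
  if (!is.finite(base0)) base0 <- y[1L]
  ipk <- which.max(abs(y - base0))
  amp <- y[ipk] - base0
  t0 <- t[ipk] - 0.1
  span <- max(t) - t[ipk]
  tau <- switch(n_components,
                `1` = span / 3,
                `2` = c(span / 30, span / 3),
                `3` = c(span / 100, span / 10, span / 2))
  a <- rep(amp / n_components, n_components)
  g <- list(t0 = t0, irf_fwhm = 0.15, tau = tau, a = a, baseline = base0)
  if (!is.null(init)) for (k in names(init)) g[[k]] <- init[[k]]
  stopifnot(length(g$tau) == n_components, length(g$a) == n_components)
  g
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> '%s': t0 = %.4g ps, IRF FWHM = %.4g ps%s\n",
              x$label, x$t0_ps, x$irf_fwhm_ps,
              if (x$converged) "" else " [NOT CONVERGED]"))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  tau%d = %.4g ps (a = %.4g)\n", i,
                x$components$tau_ps[i], x$components$a[i]))
  }
  cat(sprintf("  baseline %.4g, residual rms %.4g, n_boot %d\n",
              x$baseline, x$residual_rms, x$n_boot))
  if (isTRUE(x$collinear_taus)) {
    cat("  caveat: time constants are collinear (ratio < 2); amplitudes are\n",
        "  not individually identifiable\n", sep = "")
  }
  invisible(x)
}

#' Compare kinetic fits of the same trace by parsimony
#'
#' Ranks fits with different numbers of exponential components by the
#' small-sample-corrected Akaike information criterion
#' \eqn{AICc = n \log(RSS/n) + 2k + 2k(k+1)/(n-k-1)} computed from the
#' weighted residual sum of squares, and flags components whose amplitude
#' 68% bootstrap interval spans zero (weak components).
#'
#' @param fits List of [fit_trace] results for the same trace.
#' @return Object of class \code{kinetic_model_comparison}: a data frame
#'   \code{table} (one row per fit: components, rss, residual_rms, aicc,
#'   delta_aicc, weak components) and \code{best}, the index of the
#'   lowest-AICc fit.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "biexp_fit")))
  n <- vapply(fits, function(f) f$n, 1)
  if (length(unique(n)) != 1L) stop("fits are not of the same trace", call. = FALSE)
  k <- vapply(fits, function(f) f$n_par, 1)
  rss <- vapply(fits, function(f) f$rss, 1)
  aicc <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / pmax(n - k - 1, 1)
  weak <- vapply(fits, function(f) {
    flags <- weak_components(f)
    if (length(flags) == 0) "" else paste(flags, collapse = ",")
  }, "")
  tab <- data.frame(
    n_components = vapply(fits, function(f) nrow(f$components), 1),
    n_par = k, rss = rss,
    residual_rms = vapply(fits, function(f) f$residual_rms, 1),
    aicc = aicc, delta_aicc = aicc - min(aicc), weak_components = weak)
  structure(list(table = tab, best = which.min(aicc)),
            class = "kinetic_model_comparison")
}

#' Flag fit components whose amplitude is consistent with zero
#'
#' A component counts as weak when its amplitude is consistent with zero at
#' the requested confidence level (default: the conventional two-sided 95%,
#' i.e. \eqn{|a| < 1.96\,\sigma_a}), using the linearized covariance sigma,
#' which is wide when components are collinear. When a bootstrap was run,
#' a 68% bootstrap interval spanning zero also counts (an even weaker
#' component: note that a residual bootstrap regenerates data from the
#' fitted, possibly overfitted, curve and so tends to re-find a spurious
#' component; the linearized sigma is the sharper overfitting diagnostic).
#'
#' @param fit A [fit_trace] result.
#' @param level Two-sided confidence level of the consistent-with-zero test.
#' @return Integer vector of component indices (tau-ascending order) whose
#'   amplitude is consistent with 0.
#' @export
weak_components <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "biexp_fit"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  nc <- nrow(fit$components)
  out <- integer()
  for (i in seq_len(nc)) {
    a <- fit$components$a[i]
    s <- fit$components$a_sigma[i]
    weak <- is.finite(s) && abs(a) <= z * s
    if (!weak && !is.null(fit$ci68)) {
      ci <- fit$ci68[, paste0("a", i)]
      weak <- ci[1L] <= 0 && ci[2L] >= 0
    }
    if (weak) out <- c(out, i)
  }
  out
}

#' @export
print.kinetic_model_comparison <- function(x, ...) {
  cat("<kinetic_model_comparison>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("preferred: fit %d (lowest AICc)\n", x$best))
  for (i in seq_len(nrow(x$table))) {
    if (nzchar(x$table$weak_components[i])) {
      cat(sprintf("  caveat: fit %d component(s) %s have amplitude consistent with 0\n",
                  i, x$table$weak_components[i]))
    }
  }
  invisible(x)
}
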