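#' Build a laser-on minus laser-off transient spectrum
#'
#' Restricts to the overlap of the two grids, resamples the laser-off
#' spectrum onto the laser-on grid ([resample]) and subtracts. Uncertainties
#' are propagated in quadrature when both spectra carry them.
#'
#' @param on,off [energy_spectrum]s of the same channel with overlapping
#'   energy ranges.
#' @return A [transient_spectrum] on the (restricted) laser-on grid, with
#'   the laser-on delay.
#' @export
make_transient <- function(on, off) {
  validate_energy_spectrum(on)
  validate_energy_spectrum(off)
  if (on$channel != off$channel) {
    stop("spectra are from different channels", call. = FALSE)
  }
  lo <- max(min(on$energy_ev), min(off$energy_ev))
  hi <- min(max(on$energy_ev), max(off$energy_ev))
  if (lo >= hi) stop("energy ranges do not overlap", call. = FALSE)
  keep <- on$energy_ev >= lo & on$energy_ev <= hi
  if (sum(keep) < 2L) stop("energy ranges do not overlap", call. = FALSE)
  grid <- on$energy_ev[keep]
  off_r <- resample(off, grid)
  delta <- on$intensity[keep] - off_r$intensity
  sigma <- if (!is.null(on$sigma) && !is.null(off_r$sigma)) {
    sqrt(on$sigma[keep]^2 + off_r$sigma^2)
  } else NULL
  transient_spectrum(grid, delta, sigma = sigma, delay_ps = on$delay_ps,
                     channel = on$channel)
}

#' Normalize a transient spectrum to unit maximum amplitude
#'
#' Scales \code{delta} (and \code{sigma}) so that \eqn{\max|\delta| = 1} and
#' sets the \code{normalized} flag. Idempotent and invariant under positive
#' rescaling of the input.
#'
#' @param t A [transient_spectrum] with nonzero \code{delta}.
#' @return The normalized [transient_spectrum].
#' @export
normalize_to_max <- function(t) {
  validate_transient_spectrum(t)
  m <- max(abs(t$delta))
  if (m == 0) stop("cannot normalize an all-zero transient", call. = FALSE)
  t$delta <- t$delta / m
  if (!is.null(t$sigma)) t$sigma <- t$sigma / m
  t$normalized <- TRUE
  t
}

#' Best energy shift (and scale) matching one transient onto another
#'
#' Finds the shift minimizing the RMS of \eqn{a(E) - s\, b(E + \Delta)} over
#' the overlap region: a coarse grid search at 0.05 eV resolution followed
#' by parabolic refinement around the minimum. With \code{allow_scale} the
#' scale \eqn{s} is the least-squares optimum at each trial shift, otherwise
#' 1. A positive shift moves \code{b} to higher energy.
#'
#' @param a,b [transient_spectrum]s.
#' @param shift_range Length-2 numeric, allowed shift interval (eV).
#' @param allow_scale Logical; fit a free amplitude scale.
#' @param step_ev Grid-search resolution (eV).
#' @return List with \code{shift_ev}, \code{scale}, \code{rms}.
#' @export
best_shift <- function(a, b, shift_range = c(-3, 3), allow_scale = TRUE,
                       step_ev = 0.05) {
  validate_transient_spectrum(a)
  validate_transient_spectrum(b)
  span_a <- diff(range(a$energy_ev))
  rms_at <- function(shift) {
    eb <- b$energy_ev + shift
    lo <- max(min(a$energy_ev), min(eb))
    hi <- min(max(a$energy_ev), max(eb))
    keep <- a$energy_ev >= lo & a$energy_ev <= hi
    if (hi - lo < 0.5 * span_a || sum(keep) < 3L) return(c(NA_real_, NA_real_))
    av <- a$delta[keep]
    bv <- stats::approx(eb, b$delta, xout = a$energy_ev[keep])$y
    s <- if (allow_scale) {
      d <- sum(bv^2)
      if (d == 0) 0 else sum(av * bv) / d
    } else 1
    c(sqrt(mean((av - s * bv)^2)), s)
  }
  shifts <- seq(shift_range[1L], shift_range[2L], by = step_ev)
  vals <- vapply(shifts, function(s) rms_at(s)[1L], 1)
  if (all(is.na(vals))) {
    stop("no shift in range leaves >= 50% overlap", call. = FALSE)
  }
  i <- which.min(vals)
  # parabolic refinement through the three points around the grid minimum
  shift <- shifts[i]
  if (i > 1L && i < length(shifts) &&
      !is.na(vals[i - 1L]) && !is.na(vals[i + 1L])) {
    denom <- vals[i - 1L] - 2 * vals[i] + vals[i + 1L]
    if (denom > 0) {
      shift <- shifts[i] + step_ev * 0.5 * (vals[i - 1L] - vals[i + 1L]) / denom
    }
  }
  out <- rms_at(shift)
  if (is.na(out[1L]) || out[1L] > vals[i]) {  # refinement fell off a ledge
    shift <- shifts[i]
    out <- rms_at(shift)
  }
  list(shift_ev = shift, scale = out[2L], rms = out[1L])
}

#' Integrate transient spectra over an energy window along a delay scan
#'
#' Trapezoidal integral of \code{delta} over the window for each transient,
#' returned as a kinetic trace versus delay. Uncertainties combine the point
#' sigmas in quadrature with the trapezoidal step weights.
#'
#' @param series List of [transient_spectrum]s (one per delay, delays set).
#' @param window Length-2 numeric, integration window (eV); must lie inside
#'   every transient's grid.
#' @param label Trace label; defaults to the window.
#' @return A [kinetic_trace] (sorted by delay).
#' @export
integrate_window <- function(series, window, label = NULL) {
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, TRUE, "transient_spectrum")))
  window <- sort(as.numeric(window))
  vals <- vapply(series, function(tr) {
    if (window[1L] < min(tr$energy_ev) || window[2L] > max(tr$energy_ev)) {
      stop("integration window outside transient grid", call. = FALSE)
    }
    keep <- tr$energy_ev >= window[1L] & tr$energy_ev <= window[2L]
    e <- tr$energy_ev[keep]
    v <- trapz_int(e, tr$delta[keep])
    s <- if (is.null(tr$sigma)) NA_real_ else {
      dw <- trapz_weights(e)
      sqrt(sum((dw * tr$sigma[keep])^2))
    }
    c(v, s)
  }, c(0, 0))
  delays <- vapply(series, function(tr) tr$delay_ps, 1)
  ord <- order(delays)
  sig <- vals[2L, ord]
  kinetic_trace(delays[ord], vals[1L, ord],
                sigma = if (anyNA(sig)) NULL else sig,
                label = label %||%
                  sprintf("integral [%.6g, %.6g] eV", window[1L], window[2L]))
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1L] <- (x[2L] - x[1L]) / 2
  w[n] <- (x[n] - x[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  w
}
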