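#' Energy spectrum container
#'
#' An \code{energy_spectrum} holds one emission or absorption spectrum on a
#' strictly ascending photon-energy grid, together with the acquisition
#' metadata the downstream analysis needs: the detection channel
#' (\code{"kalpha"}, \code{"kbeta"} or \code{"xanes"}), the pump-laser state
#' (\code{"on"}, \code{"off"} or \code{"na"} for steady state) and the
#' pump-probe delay in picoseconds.
#'
#' @param energy_ev Numeric vector of photon energies (eV), strictly
#'   increasing.
#' @param intensity Numeric vector of signal values, same length as
#'   \code{energy_ev} (arbitrary counts).
#' @param sigma Optional numeric vector of per-point 1-sigma uncertainties,
#'   same length and units as \code{intensity}; must be strictly positive.
#' @param channel One of \code{"kalpha"}, \code{"kbeta"}, \code{"xanes"}.
#' @param laser_state One of \code{"on"}, \code{"off"}, \code{"na"}.
#' @param delay_ps Pump-probe delay in ps, or \code{NA} for steady-state
#'   spectra.
#'
#' @return An object of class \code{energy_spectrum}: a list with fields
#'   \code{energy_ev}, \code{intensity}, \code{sigma}, \code{channel},
#'   \code{laser_state}, \code{delay_ps}.
#' @export
#' @examples
#' e <- seq(6380, 6420, by = 0.2)
#' s <- energy_spectrum(e, exp(-(e - 6404)^2 / 8), channel = "kalpha")
#' s
energy_spectrum <- function(energy_ev, intensity, sigma = NULL,
                            channel = c("kalpha", "kbeta", "xanes"),
                            laser_state = c("na", "on", "off"),
                            delay_ps = NA_real_) {
  channel <- match.arg(channel)
  laser_state <- match.arg(laser_state)
  obj <- structure(
    list(energy_ev = as.numeric(energy_ev),
         intensity = as.numeric(intensity),
         sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
         channel = channel, laser_state = laser_state,
         delay_ps = as.numeric(delay_ps)),
    class = "energy_spectrum")
  validate_energy_spectrum(obj)
  obj
}

validate_energy_spectrum <- function(x) {
  stopifnot(inherits(x, "energy_spectrum"))
  e <- x$energy_ev
  if (length(e) < 2L || anyNA(e)) {
    stop("energy grid must have >= 2 finite points", call. = FALSE)
  }
  d <- diff(e)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L]
    stop(sprintf(
      "energy grid must be strictly increasing; violated between rows %d and %d (%.6g >= %.6g eV)",
      bad, bad + 1L, e[bad], e[bad + 1L]), call. = FALSE)
  }
  if (length(x$intensity) != length(e)) {
    stop("intensity and energy grid lengths differ", call. = FALSE)
  }
  if (!is.null(x$sigma)) {
    if (length(x$sigma) != length(e)) {
      stop("sigma and energy grid lengths differ", call. = FALSE)
    }
    if (any(!is.finite(x$sigma)) || any(x$sigma <= 0)) {
      stop("sigma must be strictly positive", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.energy_spectrum <- function(x, ...) {
  rng <- range(x$energy_ev)
  cat(sprintf("<energy_spectrum> %s, laser %s, %d points, %.1f-%.1f eV",
              x$channel, x$laser_state, length(x$energy_ev), rng[1], rng[2]))
  if (!is.na(x$delay_ps)) cat(sprintf(", delay %.4g ps", x$delay_ps))
  if (!is.null(x$sigma)) cat(", with uncertainties")
  cat("\n")
  invisible(x)
}

#' Transient (laser-on minus laser-off) difference spectrum
#'
#' @param energy_ev Common energy grid (eV), strictly increasing.
#' @param delta On-minus-off signal per energy point.
#' @param sigma Optional propagated 1-sigma uncertainty.
#' @param delay_ps Pump-probe delay (ps).
#' @param normalized Logical; whether \code{delta} has been scaled to unit
#'   maximum absolute amplitude.
#' @param channel Detection channel the difference was formed in.
#'
#' @return An object of class \code{transient_spectrum}.
#' @export
transient_spectrum <- function(energy_ev, delta, sigma = NULL,
                               delay_ps = NA_real_, normalized = FALSE,
                               channel = c("kalpha", "kbeta", "xanes")) {
  channel <- match.arg(channel)
  obj <- structure(
    list(energy_ev = as.numeric(energy_ev), delta = as.numeric(delta),
         sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
         delay_ps = as.numeric(delay_ps), normalized = isTRUE(normalized),
         channel = channel),
    class = "transient_spectrum")
  validate_transient_spectrum(obj)
  obj
}

validate_transient_spectrum <- function(x) {
  stopifnot(inherits(x, "transient_spectrum"))
  e <- x$energy_ev
  if (any(diff(e) <= 0)) stop("energy grid must be strictly increasing", call. = FALSE)
  if (length(x$delta) != length(e)) stop("delta and grid lengths differ", call. = FALSE)
  if (!is.null(x$sigma) && length(x$sigma) != length(e)) {
    stop("sigma and grid lengths differ", call. = FALSE)
  }
  if (x$normalized && abs(max(abs(x$delta)) - 1) > 1e-12) {
    stop("normalized flag set but max |delta| != 1", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.transient_spectrum <- function(x, ...) {
  cat(sprintf("<transient_spectrum> %s, %d points, max |delta| = %.4g%s",
              x$channel, length(x$energy_ev), max(abs(x$delta)),
              if (x$normalized) " (normalized)" else ""))
  if (!is.na(x$delay_ps)) cat(sprintf(", delay %.4g ps", x$delay_ps))
  cat("\n")
  invisible(x)
}

#' Kinetic trace: a scalar observable versus pump-probe delay
#'
#' @param delay_ps Strictly increasing delays (ps).
#' @param signal Observable value per delay.
#' @param sigma Optional per-point 1-sigma uncertainty.
#' @param label Free-text description of the observable, e.g.
#'   \code{"XANES@7125.3eV"} or \code{"Kalpha1 FWHM"}.
#'
#' @return An object of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(delay_ps, signal, sigma = NULL, label = "") {
  obj <- structure(
    list(delay_ps = as.numeric(delay_ps), signal = as.numeric(signal),
         sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
         label = as.character(label)),
    class = "kinetic_trace")
  validate_kinetic_trace(obj)
  obj
}

validate_kinetic_trace <- function(x) {
  stopifnot(inherits(x, "kinetic_trace"))
  if (any(diff(x$delay_ps) <= 0)) {
    stop("delays must be strictly increasing", call. = FALSE)
  }
  if (length(x$signal) != length(x$delay_ps)) {
    stop("signal and delay lengths differ", call. = FALSE)
  }
  if (!is.null(x$sigma) && length(x$sigma) != length(x$delay_ps)) {
    stop("sigma and delay lengths differ", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> '%s', %d delays, %.3g to %.3g ps\n",
              x$label, length(x$delay_ps), min(x$delay_ps), max(x$delay_ps)))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read a spectrum from a delimited text file
#'
#' Files are columnar (energy, intensity[, sigma]) with optional
#' \code{'#'}-prefixed header lines carrying \code{key: value} metadata
#' (\code{channel}, \code{laser_state}, \code{delay_ps}). Tab-separated by
#' default; comma-separated with \code{dialect = "csv"}.
#'
#' @param path File path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param channel,laser_state,delay_ps Defaults used when the header does not
#'   carry the corresponding key.
#' @return An [energy_spectrum].
#' @export
read_spectrum <- function(path, dialect = c("tsv", "csv"),
                          channel = "kalpha", laser_state = "na",
                          delay_ps = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- parse_header_meta(hdr)
  if (!is.null(meta$channel)) channel <- meta$channel
  if (!is.null(meta$laser_state)) laser_state <- meta$laser_state
  if (!is.null(meta$delay_ps)) delay_ps <- as.numeric(meta$delay_ps)
  sep <- if (dialect == "tsv") "\t" else ","
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  tab <- utils::read.table(text = body, sep = sep, header = FALSE,
                           colClasses = "numeric")
  if (ncol(tab) < 2L) stop("need >= 2 numeric columns in ", path, call. = FALSE)
  energy_spectrum(tab[[1L]], tab[[2L]],
                  sigma = if (ncol(tab) >= 3L) tab[[3L]] else NULL,
                  channel = channel, laser_state = laser_state,
                  delay_ps = delay_ps)
}

parse_header_meta <- function(hdr) {
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  meta
}

#' Write a spectrum to a tab-separated text file
#'
#' Writes metadata as a \code{'#'} header followed by 2 or 3 tab-separated
#' numeric columns at 15 significant digits, re-readable by
#' [read_spectrum] without loss.
#'
#' @param spectrum An [energy_spectrum].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_spectrum <- function(spectrum, path) {
  validate_energy_spectrum(spectrum)
  hdr <- c(sprintf("# channel: %s", spectrum$channel),
           sprintf("# laser_state: %s", spectrum$laser_state))
  if (!is.na(spectrum$delay_ps)) {
    hdr <- c(hdr, sprintf("# delay_ps: %.15g", spectrum$delay_ps))
  }
  cols <- list(spectrum$energy_ev, spectrum$intensity)
  if (!is.null(spectrum$sigma)) cols <- c(cols, list(spectrum$sigma))
  rows <- do.call(paste, c(lapply(cols, function(v) sprintf("%.15g", v)),
                           sep = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Resample a spectrum onto a new energy grid
#'
#' Linear interpolation of intensity (and sigma, when present) onto
#' \code{grid}. The target grid must lie within the source range; no
#' extrapolation is performed, and no smoothing is applied anywhere in I/O
#' (smoothing would bias FWHM extraction downstream).
#'
#' @param spectrum An [energy_spectrum].
#' @param grid Target energies (eV), strictly increasing, inside the source
#'   range.
#' @return An [energy_spectrum] on \code{grid}.
#' @export
resample <- function(spectrum, grid) {
  validate_energy_spectrum(spectrum)
  grid <- as.numeric(grid)
  rng <- range(spectrum$energy_ev)
  if (min(grid) < rng[1L] || max(grid) > rng[2L]) {
    stop(sprintf("target grid [%.6g, %.6g] outside source range [%.6g, %.6g] eV",
                 min(grid), max(grid), rng[1L], rng[2L]), call. = FALSE)
  }
  intensity <- stats::approx(spectrum$energy_ev, spectrum$intensity,
                             xout = grid, method = "linear")$y
  sigma <- if (is.null(spectrum$sigma)) NULL else {
    stats::approx(spectrum$energy_ev, spectrum$sigma, xout = grid)$y
  }
  energy_spectrum(grid, intensity, sigma = sigma, channel = spectrum$channel,
                  laser_state = spectrum$laser_state,
                  delay_ps = spectrum$delay_ps)
}
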