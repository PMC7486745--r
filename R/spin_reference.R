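#' Reference difference spectrum between two species
#'
#' Difference of two steady-state spectra (e.g. a high-spin reference
#' complex minus a low-spin one), normalized to unit maximum amplitude, for
#' use as a spin fingerprint in [match_spin].
#'
#' @param a,b [energy_spectrum]s of the same channel with overlapping grids.
#' @return A normalized [transient_spectrum] (a minus b).
#' @export
reference_difference <- function(a, b) {
  d <- make_transient(a, b)
  if (max(abs(d$delta)) == 0) {
    stop("reference difference is identically zero", call. = FALSE)
  }
  normalize_to_max(d)
}

#' Build the packaged toy spin-reference library
#'
#' Difference fingerprints generated from the synthetic species line models
#' (no digitized literature spectra are shipped): high-spin minus low-spin
#' and intermediate-spin minus low-spin, for one emission channel.
#'
#' @param channel \code{"kbeta"} (default) or \code{"kalpha"}.
#' @param model A [species_line_model].
#' @param grid Energy grid; defaults to [default_grid].
#' @return Named list of normalized [transient_spectrum]s
#'   (\code{"HS-LS"}, \code{"IS-LS"}).
#' @export
toy_reference_library <- function(channel = c("kbeta", "kalpha"),
                                  model = species_line_model(),
                                  grid = NULL) {
  channel <- match.arg(channel)
  if (is.null(grid)) grid <- default_grid(channel)
  ls <- species_spectrum(channel, "LS", grid, model)
  list("HS-LS" = reference_difference(species_spectrum(channel, "HS", grid, model), ls),
       "IS-LS" = reference_difference(species_spectrum(channel, "IS", grid, model), ls))
}

#' Rank reference fingerprints against a measured transient
#'
#' For each labelled reference difference spectrum, finds the best energy
#' shift and amplitude scale ([best_shift]) and ranks the references by the
#' residual RMS over the overlap. When the top two residuals differ by less
#' than 10% the assignment is flagged ambiguous: visually similar
#' fingerprints (e.g. S = 3/2 vs S = 5/2 at comparable line parameters)
#' cannot be told apart this way.
#'
#' @param transient A [transient_spectrum].
#' @param library Non-empty named list of reference [transient_spectrum]s.
#' @param shift_range Allowed shift interval (eV).
#' @return Object of class \code{spin_match}: data frame \code{ranking}
#'   (label, shift_ev, scale, rms, in ascending rms order) plus
#'   \code{ambiguous} (logical) and \code{best} (top label).
#' @export
match_spin <- function(transient, library, shift_range = c(-3, 3)) {
  validate_transient_spectrum(transient)
  stopifnot(length(library) >= 1)
  if (is.null(names(library)) || any(!nzchar(names(library)))) {
    stop("library must be a named list", call. = FALSE)
  }
  rows <- lapply(names(library), function(lab) {
    m <- best_shift(transient, library[[lab]], shift_range = shift_range,
                    allow_scale = TRUE)
    data.frame(label = lab, shift_ev = m$shift_ev, scale = m$scale,
               rms = m$rms)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$rms), , drop = FALSE]
  rownames(tab) <- NULL
  amb <- nrow(tab) >= 2L &&
    (tab$rms[2L] - tab$rms[1L]) < 0.10 * max(tab$rms[2L], .Machine$double.eps)
  structure(list(ranking = tab, ambiguous = amb, best = tab$label[1L]),
            class = "spin_match")
}

#' @export
print.spin_match <- function(x, ...) {
  cat("<spin_match>\n")
  print(x$ranking, row.names = FALSE)
  cat(sprintf("best: %s%s\n", x$best,
              if (x$ambiguous) " (ambiguous: top residuals within 10%)" else ""))
  invisible(x)
}
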