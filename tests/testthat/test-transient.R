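make_pair <- function(delay = 0.2, noise = 0, f_exc = 0.3, grid = NULL) {
  p <- cascade_params(0, 0.14, 0.61, 8.7, f_exc)
  synth_timeseries("kalpha", p, delays = delay, noise_level = noise,
                   grid = grid)[[1]]
}

test_that("on = off gives the zero transient and subtraction is antisymmetric", {
  pair <- make_pair()
  z <- make_transient(pair$off, pair$off)
  expect_true(all(z$delta == 0))
  ab <- make_transient(pair$on, pair$off)
  ba <- make_transient(pair$off, pair$on)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-14)
  bad <- energy_spectrum(seq(7100, 7150, 1), rep(1, 51), channel = "xanes")
  expect_error(make_transient(pair$on, bad), "different channels")
})

test_that("the synthetic K-alpha transient has the canonical lobe positions", {
  pair <- make_pair()
  tr <- make_transient(pair$on, pair$off)
  expect_equal(tr$energy_ev[which.max(tr$delta)], 6406, tolerance = 0.3)
  expect_equal(tr$energy_ev[which.min(tr$delta)], 6404, tolerance = 0.3)
})

test_that("half-step offset grids reproduce the analytic profile difference", {
  # fine grid: the comparison isolates the subtraction, not interpolation
  # error on a coarsely sampled peak
  p <- cascade_params(0, 0.14, 0.61, 8.7, 0.3)
  g_on <- default_grid("kalpha", 0.05)
  g_off <- g_on + 0.025
  g_off <- g_off[g_off <= max(g_on)]
  on <- synth_timeseries("kalpha", p, delays = 0.2, noise_level = 0,
                         grid = g_on)[[1]]$on
  off <- synth_timeseries("kalpha", p, delays = 0.2, noise_level = 0,
                          grid = g_off)[[1]]$off
  tr <- make_transient(on, off)
  exact_on <- synth_timeseries("kalpha", p, delays = 0.2, noise_level = 0,
                               grid = tr$energy_ev)[[1]]
  exact <- exact_on$on$intensity - exact_on$off$intensity
  peak <- max(on$intensity)
  expect_lt(max(abs(tr$delta - exact)), 1e-3 * peak)
})

test_that("normalization is idempotent and scale invariant", {
  pair <- make_pair()
  tr <- make_transient(pair$on, pair$off)
  n1 <- normalize_to_max(tr)
  expect_equal(max(abs(n1$delta)), 1)
  expect_true(n1$normalized)
  expect_equal(normalize_to_max(n1)$delta, n1$delta)
  tr5 <- tr
  tr5$delta <- 5 * tr$delta
  expect_equal(normalize_to_max(tr5)$delta, n1$delta, tolerance = 1e-14)
  zero <- transient_spectrum(1:10, rep(0, 10))
  expect_error(normalize_to_max(zero), "all-zero")
})

test_that("best_shift recovers constructed shifts and scales", {
  pair <- make_pair(grid = default_grid("kalpha", 0.1))
  a <- make_transient(pair$on, pair$off)
  b <- a
  b$energy_ev <- b$energy_ev + 2.0  # b red-shifted view: needs shift -2
  m <- best_shift(a, b, shift_range = c(-3, 3))
  expect_equal(m$shift_ev, -2.0, tolerance = 0.01)
  b2 <- a
  b2$delta <- 0.5 * a$delta
  m2 <- best_shift(a, b2, allow_scale = TRUE)
  expect_equal(m2$scale, 2.0, tolerance = 1e-6)
  expect_equal(m2$shift_ev, 0.0, tolerance = 0.01)
  self <- best_shift(a, a)
  expect_equal(self$shift_ev, 0, tolerance = 1e-9)
  expect_equal(self$scale, 1, tolerance = 1e-12)
  expect_equal(self$rms, 0, tolerance = 1e-12)
})

test_that("shift recovery survives 5% noise to within 0.1 eV", {
  pair <- make_pair(grid = default_grid("kalpha", 0.1))
  a0 <- make_transient(pair$on, pair$off)
  peak <- max(abs(a0$delta))
  errs <- vapply(seq_len(100), function(s) {
    set.seed(s)
    a <- a0
    b <- a0
    a$delta <- a$delta + rnorm(length(a$delta), sd = 0.05 * peak)
    b$delta <- b$delta + rnorm(length(b$delta), sd = 0.05 * peak)
    b$energy_ev <- b$energy_ev + 1.5
    best_shift(a, b, shift_range = c(-3, 3))$shift_ev - (-1.5)
  }, 1)
  expect_lt(stats::quantile(abs(errs), 0.9), 0.1)
})

test_that("window integration is linear, additive and guards its window", {
  zeros <- lapply(c(0.1, 0.5), function(d) {
    transient_spectrum(seq(6380, 6420, 0.2), rep(0, 201), delay_ps = d)
  })
  expect_true(all(integrate_window(zeros, c(6390, 6410))$signal == 0))
  pair <- make_pair()
  trs <- list(make_transient(pair$on, pair$off))
  whole <- integrate_window(trs, c(6390, 6410))$signal
  left <- integrate_window(trs, c(6390, 6404))$signal
  right <- integrate_window(trs, c(6404, 6410))$signal
  expect_equal(left + right, whole, tolerance = 1e-12)
  expect_error(integrate_window(trs, c(6300, 6400)), "outside")
})

test_that("the full-grid transient integral vanishes at every delay", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 0.3)
  g <- default_grid("kalpha")
  ser <- synth_timeseries("kalpha", p, delays = c(0.2, 0.5, 1, 5, 20),
                          noise_level = 0, grid = g)
  trs <- lapply(ser, function(x) make_transient(x$on, x$off))
  tot <- integrate_window(trs, range(g))
  peak <- max(ser[[1]]$off$intensity)
  expect_true(all(abs(tot$signal) < 1e-6 * peak))
})

test_that("the positive lobe rises slower than the negative lobe", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 0.3)
  ser <- synth_timeseries("kalpha", p, delays = default_delays(),
                          noise_level = 0)
  trs <- lapply(ser, function(x) make_transient(x$on, x$off))
  neg <- integrate_window(trs, c(6402, 6405))
  pos <- integrate_window(trs, c(6405, 6408))
  # model-free: the positive lobe peaks later
  expect_gt(pos$delay_ps[which.max(abs(pos$signal))],
            neg$delay_ps[which.max(abs(neg$signal))])
  # fitted: the positive lobe has the smaller (more negative) fast weight,
  # i.e. more of its rise is fed through the intermediate state
  ini <- list(t0 = 0, irf_fwhm = 0.14, tau = c(0.61, 8.7))
  f_neg <- fit_trace(kinetic_trace(neg$delay_ps, -neg$signal, label = "neg"),
                     2, init = ini, n_boot = 0)
  f_pos <- fit_trace(pos, 2, init = ini, n_boot = 0)
  frac <- function(f) f$components$a[1] / sum(f$components$a)
  expect_lt(frac(f_pos), frac(f_neg))
})
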