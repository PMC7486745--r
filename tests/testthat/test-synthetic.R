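test_that("spin states carry the unpaired-electron bookkeeping", {
  expect_equal(spin_state("LS")$n_unpaired, 1L)
  expect_equal(spin_state("IS")$two_S, 3L)
  expect_equal(spin_state("HS")$n_unpaired, 5L)
  expect_error(spin_state("S2"))
})

test_that("K-alpha species spectra peak at the canonical doublet energies", {
  g <- default_grid("kalpha", 0.05)
  for (st in c("LS", "IS", "HS")) {
    s <- species_spectrum("kalpha", st, g)
    i1 <- which.max(s$intensity)
    expect_equal(s$energy_ev[i1], 6404, tolerance = 0.1)
    lower <- s$energy_ev < 6397
    i2 <- which.max(s$intensity[lower])
    expect_equal(s$energy_ev[lower][i2], 6391, tolerance = 0.1)
    # Kalpha2:Kalpha1 peak ratio ~ 1:2
    expect_equal(s$intensity[lower][i2] / s$intensity[i1], 0.5,
                 tolerance = 0.05)
  }
})

test_that("K-alpha1 width follows the spin-ordering law with saturation", {
  m <- species_line_model()
  f <- vapply(c("LS", "IS", "HS"),
              function(st) numeric_fwhm(species_doublet(st, m)$line1), 1)
  expect_lt(f[["LS"]], f[["IS"]])
  expect_lte(f[["IS"]], f[["HS"]] + 1e-9)
  expect_equal(f[["HS"]] - f[["LS"]], m$kalpha_broadening_ev,
               tolerance = 1e-6)
  expect_equal(f[["IS"]] - f[["LS"]], m$kalpha_broadening_ev,
               tolerance = 1e-6)
})

test_that("K-beta spin signature has the mainline/sideband sign pattern", {
  g <- default_grid("kbeta", 0.1)
  ls <- species_spectrum("kbeta", "LS", g)
  hs <- species_spectrum("kbeta", "HS", g)
  d <- hs$intensity - ls$intensity
  expect_lt(d[which.min(abs(g - 7058))], 0)
  expect_gt(d[which.min(abs(g - 7043))], 0)
})

test_that("excited-state spectra conserve the grid-integrated intensity", {
  g <- default_grid("kalpha")
  ls <- species_spectrum("kalpha", "LS", g)
  for (st in c("IS", "HS")) {
    s <- species_spectrum("kalpha", st, g)
    expect_equal(spincascade:::trapz_int(g, s$intensity),
                 spincascade:::trapz_int(g, ls$intensity),
                 tolerance = 1e-10)
  }
})

test_that("populations vanish pre-pump and the cycle closes", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 0.3)
  pop <- simulate_populations(p, delays = c(-5, -2, 150, 200))
  early <- pop$delay_ps < 0
  expect_true(all(abs(pop$n_is[early]) < 1e-12))
  expect_true(all(abs(pop$n_gs[early] - 1) < 1e-12))
  late <- pop$delay_ps > 10 * p$tau3_ps
  expect_true(all(pop$n_is[late] + pop$n_hs[late] < 1e-6))
  expect_true(all(abs(pop$n_gs[late] - 1) < 1e-6))
})

test_that("noiseless laser-on spectra equal the population-weighted mixture", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 0.3)
  g <- default_grid("kalpha")
  pair <- synth_timeseries("kalpha", p, delays = 0.2, noise_level = 0)[[1]]
  pop <- cascade_populations(0.2, p)
  mix <- (1 - pop$n_is - pop$n_hs) * species_spectrum("kalpha", "LS", g)$intensity +
    pop$n_is * species_spectrum("kalpha", "IS", g)$intensity +
    pop$n_hs * species_spectrum("kalpha", "HS", g)$intensity
  expect_equal(pair$on$intensity, mix, tolerance = 1e-12)
  expect_equal(pair$off$intensity,
               species_spectrum("kalpha", "LS", g)$intensity,
               tolerance = 1e-12)
})

test_that("stochastic outputs are bit-identical under the same seed", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 0.3)
  a <- synth_timeseries("kalpha", p, delays = c(0.2, 1), noise_level = 0.05,
                        seed = 123)
  b <- synth_timeseries("kalpha", p, delays = c(0.2, 1), noise_level = 0.05,
                        seed = 123)
  expect_identical(a[[2]]$on$intensity, b[[2]]$on$intensity)
  t1 <- synth_kinetic_trace("xanes_amplitude", p, noise_level = 0.05,
                            seed = 9)
  t2 <- synth_kinetic_trace("xanes_amplitude", p, noise_level = 0.05,
                            seed = 9)
  expect_identical(t1$signal, t2$signal)
  expect_error(synth_timeseries("kalpha", p, noise_level = -0.1), ">= 0")
})

test_that("the ensemble noise at the transient peak matches the request", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 0.3)
  g <- seq(6384, 6412, by = 0.5)  # small grid to keep the ensemble cheap
  noise <- 0.03
  vals <- vapply(seq_len(500), function(s) {
    pair <- synth_timeseries("kalpha", p, delays = 0.2, noise_level = noise,
                             seed = s, grid = g)[[1]]
    i <- which.min(abs(g - 6404))  # at the Kalpha1 peak sigma = noise * max
    pair$off$intensity[i]
  }, 1)
  clean <- species_spectrum("kalpha", "LS", g)$intensity
  expect_equal(sd(vals), noise * max(clean), tolerance = 0.1)
})

test_that("a pure high-spin observable rises with tau1 and decays with tau3", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 1)
  tr <- synth_kinetic_trace("xanes_amplitude", p, weights = c(0, 1),
                            noise_level = 0)
  expect_equal(tr$signal, cascade_populations(tr$delay_ps, p)$n_hs,
               tolerance = 1e-12)
  # trace integral strictly increases with tau3 (longer-lived high spin)
  p2 <- cascade_params(0, 0.14, 0.61, 12, 1)
  tr2 <- synth_kinetic_trace("xanes_amplitude", p2, weights = c(0, 1),
                             noise_level = 0)
  expect_gt(sum(tr2$signal), sum(tr$signal))
})

test_that("noiseless generator traces are inverted exactly by the fitter", {
  p <- cascade_params(0.1, 0.15, 0.63, 7.8, 0.4)
  tr <- synth_kinetic_trace("kalpha_fwhm", p, noise_level = 0)
  fit <- fit_trace(tr, 2, init = list(t0 = 0, tau = c(0.4, 5)), n_boot = 0)
  expect_equal(fit$components$tau_ps, c(0.63, 7.8), tolerance = 1e-6)
  expect_equal(fit$irf_fwhm_ps, 0.15, tolerance = 1e-6)
})

test_that("weights_from_amplitudes inverts the population-to-amplitude map", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 1)
  w <- weights_from_amplitudes(0.7, 0.3, p)
  tr <- synth_kinetic_trace("xanes_amplitude", p, weights = w,
                            noise_level = 0)
  ref <- 0.7 * emg_response(tr$delay_ps, 0, 0.14, 0.61) +
    0.3 * emg_response(tr$delay_ps, 0, 0.14, 8.7)
  expect_equal(tr$signal, ref, tolerance = 1e-10)
})
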