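test_that("emg_response has the correct zero-IRF limit and causality", {
  tau <- 0.61
  # tiny IRF: value at t0 + tau approaches 1/e
  expect_equal(emg_response(tau, 0, 1e-6, tau), exp(-1), tolerance = 1e-6)
  # pre-pump causality
  s <- 0.14 / (2 * sqrt(2 * log(2)))
  expect_lt(emg_response(-5 * s - 0.5, 0, 0.14, 0.61), 1e-12)
})

test_that("emg_response equals adaptive-quadrature convolution across sigma/tau", {
  tau <- 1
  s0 <- 2 * sqrt(2 * log(2))
  for (ratio in c(0.01, 0.1, 1, 10)) {
    fwhm <- ratio * tau * s0
    t <- c(-2 * ratio, 0, 0.3, 1, 3, 8) * max(1, ratio)
    expect_equal(emg_response(t, 0, fwhm, tau), quad_conv(t, 0, fwhm, tau),
                 tolerance = 1e-8)
  }
})

test_that("emg_response stays finite for extreme width/decay ratios", {
  expect_true(all(is.finite(emg_response(c(-1, 0, 1), 0, exp(25), 1))))
  expect_true(all(is.finite(emg_response(c(-1, 0, 1), 0, 1e-9, 1e5))))
})

test_that("cascade populations match Runge-Kutta integration", {
  p <- cascade_params(0.05, 0.14, 0.61, 8.7, 0.3)
  delays <- sort(c(seq(-1, 2, by = 0.1), seq(3, 40, by = 1)))
  ode <- ode_populations(delays, p)
  cl <- cascade_populations(delays, p)
  expect_equal(cl$n_is, ode$n_is, tolerance = 1e-6)
  expect_equal(cl$n_hs, ode$n_hs, tolerance = 1e-6)
})

test_that("the degenerate tau1 = tau3 branch matches the ODE oracle", {
  p <- cascade_params(0, 0.14, 1.3, 1.3 * (1 + 1e-9), 0.5)
  delays <- seq(-0.5, 10, by = 0.1)
  ode <- ode_populations(delays, p)
  cl <- cascade_populations(delays, p)
  expect_equal(cl$n_hs, ode$n_hs, tolerance = 1e-6)
})

test_that("population bookkeeping conserves the pumped fraction", {
  p <- cascade_params(0, 0.2, 0.5, 6, 0.4)
  delays <- seq(-1, 30, by = 0.25)
  cl <- cascade_populations(delays, p)
  ode <- ode_populations(delays, p)
  # everything pumped is either still excited or tracked as recovered
  expect_equal(cl$n_is + cl$n_hs + ode$recovered, cl$pumped,
               tolerance = 1e-9)
  recovered <- cl$pumped - cl$n_is - cl$n_hs
  expect_true(all(recovered > -1e-12))
  expect_true(all(diff(recovered) > -1e-12))
})

test_that("an infinitely slow second step gives the error-function step", {
  p <- cascade_params(0, 0.14, 0.61, 1e9, 0.3)
  delays <- seq(-0.5, 6, by = 0.05)
  cl <- cascade_populations(delays, p)
  s <- 0.14 / (2 * sqrt(2 * log(2)))
  # far beyond tau1 every pumped molecule sits in the high-spin state
  late <- delays > 5 * 0.61
  expect_equal(cl$n_hs[late],
               0.3 * pnorm(delays[late], 0, s) - cl$n_is[late],
               tolerance = 1e-6)
})

test_that("the high-spin population peaks after the intermediate one", {
  for (pars in list(c(0.14, 0.61, 8.7), c(0.3, 0.2, 2), c(0.05, 3, 4))) {
    p <- cascade_params(0, pars[1], pars[2], pars[3], 0.5)
    delays <- seq(-1, 60, by = 0.02)
    cl <- cascade_populations(delays, p)
    expect_gt(delays[which.max(cl$n_hs)], delays[which.max(cl$n_is)])
  }
})

test_that("noiseless synthetic biexponentials are recovered exactly", {
  tr <- make_table_trace(xanes_truth, seed = 1, noise = 0)
  fit <- fit_trace(tr, 2, n_boot = 0)
  expect_true(fit$converged)
  expect_equal(fit$components$tau_ps, c(0.61, 8.7), tolerance = 1e-6)
  expect_equal(fit$components$a, c(0.70, 0.30), tolerance = 1e-6)
  expect_equal(fit$irf_fwhm_ps, 0.14, tolerance = 1e-6)
  expect_equal(fit$t0_ps, 0, tolerance = 1e-6)
})

test_that("fits are invariant to affine rescaling of the signal", {
  tr <- make_table_trace(xanes_truth, seed = 3, noise = 0.05)
  f1 <- fit_trace(tr, 2, n_boot = 0)
  tr2 <- kinetic_trace(tr$delay_ps, 5 * tr$signal + 2,
                       sigma = 5 * tr$sigma, label = tr$label)
  f2 <- fit_trace(tr2, 2, n_boot = 0)
  expect_equal(f2$components$tau_ps, f1$components$tau_ps, tolerance = 1e-4)
  expect_equal(f2$components$a, 5 * f1$components$a, tolerance = 1e-4)
  expect_equal(f2$baseline, 5 * f1$baseline + 2, tolerance = 1e-3)
})

test_that("a second component fit to monoexponential data is flagged weak", {
  p <- cascade_params(0, 0.14, 0.61, 8.7, 1)
  delays <- default_delays()
  set.seed(11)
  clean <- emg_response(delays, 0, 0.14, 3)
  tr <- kinetic_trace(delays, clean + rnorm(length(delays), sd = 0.03),
                      sigma = rep(0.03, length(delays)), label = "mono")
  fit <- fit_trace(tr, 2, init = list(tau = c(0.5, 5), t0 = 0), n_boot = 0)
  expect_true(length(weak_components(fit)) >= 1)
})

test_that("the information criterion prefers the true biexponential over mono", {
  n_pref <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    tr <- make_table_trace(xanes_truth, seed = 1000 + s, noise = 0.05)
    f1 <- fit_trace(tr, 1, n_boot = 0)
    f2 <- fit_trace(tr, 2, n_boot = 0)
    cmp <- compare_models(list(f1, f2))
    if (cmp$best == 2L) n_pref <- n_pref + 1
  }
  expect_gte(n_pref / n_seeds, 0.95)
})

test_that("identical fits get identical comparison scores", {
  tr <- make_table_trace(xanes_truth, seed = 2, noise = 0.05)
  f <- fit_trace(tr, 2, n_boot = 0)
  cmp <- compare_models(list(f, f))
  expect_equal(cmp$table$aicc[1], cmp$table$aicc[2])
  expect_error(compare_models(list()), "length")
})
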