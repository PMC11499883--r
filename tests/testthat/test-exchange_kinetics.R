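test_that("equilibrium abundance from water and EIE", {
  # alpha = 1: acetate equilibrates to the water itself
  expect_equal(equilibrium_abundance(-36, fractionation(alpha = 1)),
               delta_to_abundance(iso_delta(-36)))
  # 5% 2H2O medium with alpha = 0.9: hand ratio arithmetic
  w5 <- abundance_to_delta(0.05)$value
  expect_equal(equilibrium_abundance(w5, fractionation(alpha = 0.9)),
               0.0452261, tolerance = 1e-6)
  # +110 permil water, alpha 0.882: R_w = 1.5576e-4*1.110, R_e = 0.882*R_w
  R_e <- 0.882 * 1.5576e-4 * 1.110
  expect_equal(equilibrium_abundance(110, fractionation(alpha = 0.882)),
               R_e / (1 + R_e), tolerance = 1e-12)
})

test_that("noiseless rate-constant recovery is exact for any (k, F_i, F_e)", {
  cases <- list(
    list(k = 1e-6, F_i = 1.5e-4, F_e = 0.045),     # 5% medium, enriching
    list(k = 1e-6, F_i = 1.4e-4, F_e = 1.30e-4),   # depleting, small amplitude
    list(k = 3e-9, F_i = 1.5e-4, F_e = 0.045),     # slow, far from equilibrium
    list(k = 5e-5, F_i = 1.36e-4, F_e = 1.53e-4)   # fast, natural abundance
  )
  for (cs in cases) {
    t_end <- min(3 / cs$k, 2.6e6)
    s <- noiseless_series(cs$k, cs$F_i, cs$F_e, seq(0, t_end, length.out = 10))
    fit <- fit_rate_constant(s, cs$F_e)
    expect_equal(fit$k, cs$k, tolerance = 1e-6)
  }
})

test_that("near-equilibrium points are discarded and counted", {
  k <- 1e-4
  s <- noiseless_series(k, 1.5e-4, 0.045, seq(0, 8 / k, length.out = 12))
  fit <- fit_rate_constant(s, 0.045)
  # points beyond ~3 half-times (frac remaining < 5%) must be excluded
  expect_gt(fit$n_discarded, 0)
  expect_equal(fit$n_retained + fit$n_discarded, 12)
  expect_equal(fit$k, k, tolerance = 1e-6)
  # discarding never flips the slope sign on noiseless data
  expect_gt(fit$k, 0)
})

test_that("degenerate series flag and error paths", {
  flat <- exchange_series(373.15, c(0, 1e5, 2e5), c(-127, -127, -127), 0)
  fit <- fit_rate_constant(flat, 0.045)
  expect_true("no-exchange" %in% fit$flags)
  expect_equal(fit$k, 0)
  expect_error(fit_rate_constant(flat, 1.5), "invalid-abundance")
  # all but the first point inside the discard zone -> too few retained
  k <- 1e-3
  expect_error(
    fit_rate_constant(noiseless_series(k, 1.5e-4, 0.045, c(0, 1e4, 2e4)),
                      0.045),
    "insufficient-data")
  # a series already sitting exactly at equilibrium cannot be normalized
  eq_d <- abundance_to_delta(0.045)$value
  s_eq <- exchange_series(373.15, c(0, 1e4, 2e4), rep(eq_d, 3), 0)
  expect_error(
    fit_rate_constant(s_eq, delta_to_abundance(iso_delta(eq_d))),
    "degenerate")
})

test_that("noisy rate recovery: median k within 5% of truth (seeded MC)", {
  k_true <- 1e-6
  t_half <- log(2) / k_true
  times <- seq(0, 3 * t_half, length.out = 10)
  w5 <- abundance_to_delta(0.05)$value
  set.seed(101)
  ks <- replicate(200, {
    s <- simulate_exchange_series(373.15, times, w5,
                                  initial_acetate_d2H = -127,
                                  eie = fractionation(alpha = 0.9),
                                  k = k_true, noise_sd = 2)
    F_e <- equilibrium_abundance(w5, fractionation(alpha = 0.9))
    fit_rate_constant(s, F_e)$k
  })
  expect_lt(abs(stats::median(ks) / k_true - 1), 0.05)
})

test_that("half-time arithmetic", {
  expect_equal(half_time(log(2)), 1)
  expect_equal(half_time(log(2) / (3 * 3600)), 3 * 3600)
  # 810 yr <-> 2.71e-11 /s
  expect_equal(log(2) / (810 * spy()), 2.7117e-11, tolerance = 1e-4)
  expect_equal(half_time(2.7117e-11) / spy(), 810, tolerance = 1e-4)
  expect_error(half_time(0), "invalid-rate")
})

test_that("two-point Arrhenius reconstruction gives the published activation energy", {
  k200 <- log(2) / (3 * 3600)
  k60 <- log(2) / (810 * spy())
  fit <- fit_arrhenius(c(473.15, 333.15), c(k200, k60))
  expect_equal(fit$E_A / 1000, 137.40, tolerance = 1e-4)  # closed-form oracle
  expect_equal(fit$E_A / 1000, 138, tolerance = 2 / 138)  # published, +/-2
  expect_equal(fit$rmsd_lnk, 0, tolerance = 1e-10)
})

test_that("Arrhenius regression recovers exact parameters and handles edge cases", {
  E_A <- 120000; lnA <- 20
  Ts <- seq(330, 480, length.out = 8)
  ks <- exp(lnA - E_A / (rgas() * Ts))
  fit <- fit_arrhenius(Ts, ks)
  expect_equal(fit$E_A, E_A, tolerance = 1e-10)
  expect_equal(fit$lnA, lnA, tolerance = 1e-10)
  expect_equal(fit$rmsd_lnk, 0, tolerance = 1e-10)
  # identical rates at two temperatures -> E_A = 0
  expect_equal(fit_arrhenius(c(350, 450), c(1e-6, 1e-6))$E_A, 0)
  expect_error(fit_arrhenius(c(400, 400), c(1e-6, 2e-6)), "degenerate-regression")
  # simulate-and-refit with lognormal rate noise stays within the spread
  set.seed(7)
  EAs <- replicate(40, {
    fit_arrhenius(Ts, ks * exp(stats::rnorm(8, sd = 0.3)))$E_A
  })
  expect_lt(abs(stats::median(EAs) - E_A), 2 * stats::sd(EAs))
})

test_that("extrapolation reproduces the published 25 C half-time band", {
  fit <- default_arrhenius_fit()
  ex <- extrapolate_rate(fit, 298.15)
  t12_yr <- log(2) / ex$k / spy()
  expect_equal(t12_yr, 250000, tolerance = 70000 / 250000)  # published band
  expect_equal(t12_yr, 273762, tolerance = 1e-4)            # two-point oracle
  # at a calibration temperature the residual-free fit returns the input k
  expect_equal(extrapolate_rate(fit, 473.15)$k, log(2) / (3 * 3600),
               tolerance = 1e-10)
  # zero RMSD collapses the band
  expect_equal(ex$k_low, ex$k)
  expect_equal(ex$k_high, ex$k)
})

test_that("equilibration time is 4 half-times and monotone in temperature", {
  fit <- default_arrhenius_fit()
  expect_equal(equilibration_time(fit, 473.15), 4 * 3 * 3600, tolerance = 1e-8)
  Ts <- seq(280, 480, by = 10)
  eq <- vapply(Ts, function(T) equilibration_time(fit, T), numeric(1))
  expect_true(all(diff(eq) < 0))
  t12 <- vapply(Ts, function(T) half_time(extrapolate_rate(fit, T)$k), numeric(1))
  expect_true(all(diff(t12) < 0))
})
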