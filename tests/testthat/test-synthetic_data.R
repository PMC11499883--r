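test_that("forward simulation hits its end-members", {
  eie <- fractionation(alpha = 0.882)
  s <- simulate_exchange_series(473.15, 3600 * c(0, 1, 3, 6, 12, 24),
                                water_d2H = 110, initial_acetate_d2H = -127,
                                eie = eie, k = log(2) / (3 * 3600), noise_sd = 0)
  expect_equal(s$acetate_d2H[1], -127, tolerance = 1e-10)   # t = 0 exact
  # asymptote: at 8 half-times the series is within 2^-8 of equilibrium
  d_eq <- abundance_to_delta(attr(s, "F_e_true"))$value
  expect_lt(abs(s$acetate_d2H[6] - d_eq), 0.5)
  expect_true(all(diff(s$acetate_d2H) > 0))  # monotone approach from below
})

test_that("round trip: simulated 200 C series refits a 3 h half-time", {
  eie <- eie_curve()
  s <- simulate_exchange_series(473.15, 3600 * 0:24, water_d2H = 110,
                                initial_acetate_d2H = -127, eie = eie,
                                k = log(2) / (3 * 3600), noise_sd = 0)
  F_e <- equilibrium_abundance(110, eie_at(eie, 473.15))
  fit <- fit_rate_constant(s, F_e)
  expect_equal(half_time(fit$k) / 3600, 3, tolerance = 1e-6)
  # equilibrium reached within a day, as at 200 C in the laboratory
  expect_lt(abs(s$acetate_d2H[25] - abundance_to_delta(F_e)$value), 0.5)
})

test_that("fixed seeds reproduce noisy series exactly", {
  args <- list(473.15, 3600 * 0:10, water_d2H = -50,
               initial_acetate_d2H = -127, eie = fractionation(alpha = 0.882),
               k = 1e-5, noise_sd = 2, seed = 11)
  s1 <- do.call(simulate_exchange_series, args)
  s2 <- do.call(simulate_exchange_series, args)
  expect_identical(s1$acetate_d2H, s2$acetate_d2H)
  args$seed <- 12
  s3 <- do.call(simulate_exchange_series, args)
  expect_false(identical(s1$acetate_d2H, s3$acetate_d2H))
})

test_that("convergence pair brackets the EIE from both sides", {
  eie <- fractionation(alpha = 0.882)
  pair <- simulate_convergence_pair(473.15, 3600 * c(0:6, seq(12, 72, 12)),
                                    eie = eie, k = log(2) / (3 * 3600),
                                    noise_sd = 0)
  eps_end <- vapply(pair, function(s) {
    apparent_alpha(iso_delta(s$acetate_d2H[length(s$acetate_d2H)]),
                   iso_delta(s$water_d2H))$epsilon
  }, numeric(1))
  # both series' final apparent fractionation converges to the same EIE
  expect_equal(unname(eps_end), c(-118, -118), tolerance = 1e-4)
  # each converges to its own water-specific equilibrium delta
  d_end <- vapply(pair, function(s) s$acetate_d2H[length(s$acetate_d2H)], numeric(1))
  expect_false(isTRUE(all.equal(d_end[1], d_end[2], tolerance = 1)))
  # opposite initial offsets approach from opposite directions
  dir <- vapply(pair, function(s) sign(s$acetate_d2H[5] - s$acetate_d2H[1]), numeric(1))
  expect_equal(unname(dir), c(-1, 1))
})

test_that("synthetic site observations drive the clock as configured", {
  # at the equilibrium fractionation the clock reports equilibrium
  obs_eq <- simulate_site_observation(-192, water_d2H = -36, acetate_conc = 1e-3,
                                      noise_sd = 0)
  r <- assess_disequilibrium(obs_eq, fractionation(epsilon = -192))
  expect_equal(r$offset, 0, tolerance = 1e-10)
  expect_false(r$disequilibrated)
  # a -105 permil apparent fractionation is 87 permil out of equilibrium
  obs <- simulate_site_observation(-105, water_d2H = -36, acetate_conc = 1e-3,
                                   noise_sd = 0)
  r2 <- assess_disequilibrium(obs, fractionation(epsilon = -192))
  expect_equal(r2$offset, 87, tolerance = 1e-10)
  expect_true(r2$disequilibrated)
  # determinism under a fixed seed
  o1 <- simulate_site_observation(-105, -36, 1e-3, noise_sd = 2, seed = 5)
  o2 <- simulate_site_observation(-105, -36, 1e-3, noise_sd = 2, seed = 5)
  expect_identical(o1$acetate_d2H, o2$acetate_d2H)
})

test_that("noiseless campaign refit recovers the Arrhenius truth", {
  tr <- campaign_truth()
  camp <- simulate_campaign(tr$E_A, tr$lnA, noise_sd = 0)
  expect_length(camp, 8)
  res <- run_experiment_analysis(camp)
  expect_equal(res$n_failed, 0)
  expect_lt(abs(res$arrhenius$E_A - tr$E_A), 2000)
  expect_equal(res$arrhenius$E_A, tr$E_A, tolerance = 1e-6)
  t12 <- log(2) / extrapolate_rate(res$arrhenius, 298.15)$k
  expect_equal(t12, tr$half_time_25C_s, tolerance = 0.20)
})
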