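kidd_conc <- function() {
  c(acetate = 1.3e-3, sulfate = 620e-6, bicarbonate = 57e-6,
    sulfide = 10e-9, methane = 2.1e-3, water = 1)
}

test_that("reaction quotients match hand products of the site activities", {
  a <- species_activities(kidd_conc())
  sr <- default_reactions()$sulfate_reduction
  mg <- default_reactions()$methanogenesis
  expect_equal(reaction_quotient(sr, a), 4.031e-11, tolerance = 1e-3)
  expect_equal(reaction_quotient(sr, a),
               (57e-6)^2 * 10e-9 / (1.3e-3 * 620e-6), tolerance = 1e-12)
  expect_equal(reaction_quotient(mg, a), 9.208e-5, tolerance = 1e-3)
  # unit activities give Q = 1
  ones <- stats::setNames(rep(1, 6), names(kidd_conc()))
  expect_equal(reaction_quotient(sr, ones), 1)
  expect_error(reaction_quotient(sr, a[c("acetate", "sulfate")]),
               "incomplete-activities")
})

test_that("activity coefficients multiply in and default to one", {
  conc <- kidd_conc()
  a1 <- species_activities(conc)
  expect_equal(unname(a1), unname(conc))
  a2 <- species_activities(conc, gammas = c(sulfate = 0.1))
  expect_equal(unname(a2["sulfate"]), 62e-6)
  expect_equal(unname(a2["acetate"]), 1.3e-3)
  expect_error(species_activities(c(x = -1)), "positive")
})

test_that("Gibbs energy adjustment and exact scaling identity", {
  sr <- default_reactions()$sulfate_reduction
  expect_equal(gibbs_energy(sr, Q = 1), sr$dG0)
  a <- species_activities(kidd_conc())
  Q <- reaction_quotient(sr, a)
  dG <- gibbs_energy(sr, Q, 298.15)
  expect_equal(dG / 1000, -106.93, tolerance = 1e-3)  # -47.6 + RT ln Q by hand
  # equilibrium: Q = exp(-dG0/RT) zeroes dG
  Qeq <- exp(-sr$dG0 / (rgas() * 298.15))
  expect_equal(gibbs_energy(sr, Qeq, 298.15), 0, tolerance = 1e-8)
  # doubling a reactant activity (coefficient -1) halves Q: dG drops by RT ln 2
  set.seed(3)
  for (i in 1:5) {
    a2 <- a * stats::runif(length(a), 0.5, 2)
    names(a2) <- names(a)
    Q1 <- reaction_quotient(sr, a2)
    a2["acetate"] <- 2 * a2["acetate"]
    Q2 <- reaction_quotient(sr, a2)
    expect_equal(gibbs_energy(sr, Q2) - gibbs_energy(sr, Q1),
                 -rgas() * 298.15 * log(2), tolerance = 1e-10)
    # and doubling a product with coefficient +1 adds RT ln 2
    a2["sulfide"] <- 2 * a2["sulfide"]
    expect_equal(gibbs_energy(sr, reaction_quotient(sr, a2)) -
                   gibbs_energy(sr, Q2),
                 rgas() * 298.15 * log(2), tolerance = 1e-10)
  }
})

test_that("power density reproduces the published order of magnitude", {
  sr <- default_reactions()$sulfate_reduction
  a <- species_activities(kidd_conc())
  dG <- gibbs_energy(sr, reaction_quotient(sr, a))
  P <- power_density(1e-9, dG)   # 1 nM/yr floor
  expect_equal(log10(as.numeric(P)), -11.5, tolerance = 0.3 / 11.5)
  expect_equal(power_density(0, dG), 0, ignore_attr = TRUE)
  Pend <- power_density(1e-9, +5000)
  expect_equal(as.numeric(Pend), 0)
  expect_true(attr(Pend, "endergonic"))
})

test_that("cell densities span the published range and scale correctly", {
  sr <- default_reactions()$sulfate_reduction
  a <- species_activities(kidd_conc())
  P <- as.numeric(power_density(1e-9, gibbs_energy(sr, reaction_quotient(sr, a))))
  rho_mL <- supportable_cell_density(P) / 1000
  expect_true(min(rho_mL) < 1e3 && min(rho_mL) >= 1e2)
  expect_true(max(rho_mL) > 1e6 && max(rho_mL) <= 1e7)
  # monotone decreasing in maintenance power; linear in P
  expect_true(all(diff(unname(supportable_cell_density(P))) < 0))
  expect_equal(unname(supportable_cell_density(2 * P)),
               2 * unname(supportable_cell_density(P)))
  expect_error(supportable_cell_density(P, 0), "positive")
})

test_that("run_energetics composes the chain and echoes inputs", {
  res <- run_energetics(default_reactions()$methanogenesis, kidd_conc(),
                        turnover_rate_M_yr = 1e-9)
  expect_equal(log10(res$power_W_L), -12, tolerance = 0.5 / 12)
  expect_equal(res$dG0, -31000)
  expect_false(res$endergonic)
  expect_equal(length(res$cell_density_per_L), 5)
})

test_that("reaction constructor validates stoichiometry", {
  expect_error(reaction("bad", c(acetate = 0), -1), "nonzero")
  expect_error(reaction("bad", c(-1, 1), -1))
})
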