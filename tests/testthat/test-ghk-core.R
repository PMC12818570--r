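# Frozen expected values below were computed by direct evaluation of the
# closed-form Nernst/GHK expressions in a separate session (double
# precision), independent of the package code paths.

test_that("nernst_potential matches closed form and is antisymmetric", {
  expect_equal(nernst_potential(140, 140, 1, 295), 0)
  expect_equal(nernst_potential(14, 140, 1, 298.15), -59.1587, tolerance = 1e-4)
  # the canonical "about -60 mV" for a 10-fold K+ gradient at room temperature
  expect_lt(abs(nernst_potential(14, 140, 1, 298.15) - (-60)), 1)
  expect_equal(nernst_potential(19, 145, 1, 295), -51.663, tolerance = 1e-4)
  expect_equal(nernst_potential(19, 145, 1, 295),
               -nernst_potential(145, 19, 1, 295))
  # valence scaling
  expect_equal(nernst_potential(10, 1, 2, 295),
               nernst_potential(10, 1, 1, 295) / 2)
  expect_error(nernst_potential(0, 140), "positive")
  expect_error(nernst_potential(140, -1), "positive")
  expect_error(nernst_potential(140, 140, valence = 0), "valence")
})

test_that("effective_k applies the Cs+ correction additively", {
  expect_identical(effective_k(140, 5), 145)
  expect_identical(effective_k(14, 5), 19)
  expect_identical(effective_k(0, 0), 0)
  expect_error(effective_k(-1, 5), ">= 0")
})

test_that("ratio_from_erev reproduces the benchmark reversal potentials", {
  # wild type, acidic bath: printed E_rev +52.5 mV
  expect_equal(ratio_from_erev(cond_wt_acid(), 52.5)$value, 50849.2,
               tolerance = 1e-4)
  # H57Y, acidic bath: printed E_rev +32.9 mV
  expect_equal(ratio_from_erev(cond_wt_acid(), 32.9)$value, 19385.2,
               tolerance = 1e-4)
  # wild type, neutral bath, low external K+: printed E_rev -37.1 mV
  cond_n <- ionic_conditions(19, 145, ph_ex = 7.4, ph_in = 7.4,
                             temperature = T_REF)
  expect_equal(ratio_from_erev(cond_n, -37.1)$value, 480825.6,
               tolerance = 1e-4)
  # wild type, pH 6.1 bath: printed E_rev +9.2 mV
  cond_61 <- ionic_conditions(145, 145, ph_ex = 6.1, ph_in = 7.4,
                              temperature = T_REF)
  expect_equal(ratio_from_erev(cond_61, 9.2)$value, 85773.8,
               tolerance = 1e-4)
})

test_that("ratio_from_erev vanishes at E_K and rejects out-of-bracket inputs", {
  cond <- ionic_conditions(19, 145, ph_ex = 7.4, ph_in = 7.4,
                           temperature = T_REF)
  e_k <- nernst_potential(19, 145, 1, T_REF)
  expect_equal(ratio_from_erev(cond, e_k)$value, 0, tolerance = 1e-9)
  # at the H+ Nernst potential the denominator vanishes
  e_h <- nernst_potential(10^-4.7, 10^-7.4, 1, T_REF)
  expect_error(ratio_from_erev(cond_wt_acid(), e_h), "singular")
  # beyond E_H the ratio would be negative
  expect_error(ratio_from_erev(cond_wt_acid(), e_h + 20), "outside")
})

test_that("ratio_from_delta_erev reproduces K-jump benchmarks", {
  j <- k_jump(145, 19, ph_ex = 4.7, temperature = T_REF)
  expect_equal(ratio_from_delta_erev(j, -8.5)$value, 14952.2, tolerance = 1e-4)
  expect_equal(ratio_from_delta_erev(j, -3.8)$value, 38214.5, tolerance = 1e-4)
  # a pure-K channel shifts Nernstian: numerator vanishes
  d_nernst <- nernst_potential(19, 145, 1, T_REF) -
    nernst_potential(145, 145, 1, T_REF)
  expect_equal(ratio_from_delta_erev(j, d_nernst)$value, 0, tolerance = 1e-9)
  expect_error(ratio_from_delta_erev(j, 0), "singular")
  expect_error(k_jump(145, 145, 4.7), "differ")
})

test_that("erev_from_ratio limits and round-trip identity hold", {
  cond_k <- ionic_conditions(19, 145, ph_ex = 7.4, ph_in = 7.4,
                             temperature = T_REF)
  expect_equal(erev_from_ratio(cond_k, 0),
               nernst_potential(19, 145, 1, T_REF), tolerance = 1e-9)
  # very large ratio approaches the H+ Nernst potential
  e_h <- nernst_potential(10^-4.7, 10^-7.4, 1, T_REF)
  expect_equal(erev_from_ratio(cond_wt_acid(), 1e12), e_h, tolerance = 1e-3)
  # round trip over 10 orders of magnitude
  for (r in 10^seq(-2, 7, by = 0.5)) {
    e <- erev_from_ratio(cond_wt_acid(), r)
    expect_equal(ratio_from_erev(cond_wt_acid(), e)$value, r,
                 tolerance = 1e-9)
  }
  expect_equal(erev_from_ratio(cond_wt_acid(),
               ratio_from_erev(cond_wt_acid(), 52.5)$value), 52.5,
               tolerance = 1e-9)
})

test_that("ratio_from_erev is strictly increasing in E_rev on (E_K, E_H)", {
  cond <- cond_wt_acid()
  e_k <- nernst_potential(145, 145, 1, T_REF)
  e_h <- nernst_potential(10^-4.7, 10^-7.4, 1, T_REF)
  es <- seq(e_k + 0.5, e_h - 0.5, length.out = 50)
  vals <- vapply(es, function(e) ratio_from_erev(cond, e)$value, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("jump and absolute ratio equations agree on exact GHK equilibria", {
  # before/after a K jump with frozen internal pH, the equilibrium E_rev
  # values from the inversion imply the same ratio through both equations
  for (r in c(1e3, 5e4, 1e6)) {
    c1 <- ionic_conditions(145, 145, ph_ex = 4.7, ph_in = 6.0,
                           temperature = T_REF)
    c2 <- ionic_conditions(19, 145, ph_ex = 4.7, ph_in = 6.0,
                           temperature = T_REF)
    d_e <- erev_from_ratio(c2, r) - erev_from_ratio(c1, r)
    j <- k_jump(145, 19, ph_ex = 4.7, temperature = T_REF)
    expect_equal(ratio_from_delta_erev(j, d_e)$value, r, tolerance = 1e-9)
  }
})

test_that("ghk_current is thermodynamically consistent", {
  # symmetric concentrations, v = 0
  expect_equal(ghk_current(1e-10, 1, 0.145, 0.145, 0, T_REF), 0)
  # sign of current equals sign of driving force for a single ion
  e_eq <- nernst_potential(0.019, 0.145, 1, T_REF)
  for (v in c(-100, e_eq - 1, e_eq + 1, 50)) {
    i <- ghk_current(1e-10, 1, 0.145, 0.019, v, T_REF)
    expect_equal(sign(i), sign(v - e_eq))
  }
  # continuity at the v = 0 analytic limit
  expect_equal(ghk_current(1e-10, 1, 0.1, 0.2, 1e-7, T_REF),
               ghk_current(1e-10, 1, 0.1, 0.2, 0, T_REF), tolerance = 1e-6)
  # summed H+ + K+ current vanishes at the inverted zero-current voltage
  p_k <- 1e-13
  for (r in c(1e2, 5e4, 1e6)) {
    e0 <- erev_from_ratio(cond_wt_acid(), r)
    i_sum <- ghk_current(p_k * r, 1, 10^-7.4, 10^-4.7, e0, T_REF) +
      ghk_current(p_k, 1, 0.145, 0.145, e0, T_REF)
    i_ref <- abs(ghk_current(p_k, 1, 0.145, 0.145, 120, T_REF))
    expect_lt(abs(i_sum) / i_ref, 1e-9)
  }
})

test_that("permeability_from_conductance gives ohmic symmetric conductance", {
  p <- permeability_from_conductance(10, 0.145, temperature = T_REF)
  # chord conductance from the GHK current at small voltage
  i <- ghk_current(p, 1, 0.145, 0.145, 1, T_REF)   # A at 1 mV
  expect_equal(i / 1e-3 * 1e9, 10, tolerance = 1e-3) # nS
})

test_that("aggregate_geometric computes geometric mean and SD factor", {
  agg <- aggregate_geometric(c(10, 1000))
  expect_equal(agg$value, 100)
  expect_equal(agg$gsd, exp(sd(log(c(10, 1000)))))
  expect_equal(agg$n, 2L)
  agg3 <- aggregate_geometric(c(7, 7, 7))
  expect_equal(agg3$value, 7)
  expect_equal(agg3$gsd, 1)
  # seeded lognormal sample against brute-force log-space computation
  set.seed(42)
  x <- exp(rnorm(200, mean = log(5e4), sd = 0.8))
  agg_x <- aggregate_geometric(x)
  expect_equal(agg_x$value, exp(mean(log(x))))
  expect_equal(agg_x$gsd, exp(sd(log(x))))
  # accepts permeability_ratio objects
  agg_pr <- aggregate_geometric(list(permeability_ratio(10),
                                     permeability_ratio(1000)))
  expect_equal(agg_pr$value, 100)
  expect_error(aggregate_geometric(numeric(0)), "no values")
  expect_error(aggregate_geometric(c(1, -2)), "positive")
})

test_that("benchmark ratios are insensitive to room-temperature uncertainty", {
  # evaluating the printed reversal potentials at 293 K vs 298 K changes
  # the ratios by less than 8%, supporting a fixed default temperature
  cases <- list(
    list(k_ex = 145, k_in = 145, ph_ex = 4.7, e = 52.5),
    list(k_ex = 145, k_in = 145, ph_ex = 4.7, e = 32.9),
    list(k_ex = 19, k_in = 145, ph_ex = 7.4, e = -37.1),
    list(k_ex = 145, k_in = 145, ph_ex = 6.1, e = 9.2))
  for (cs in cases) {
    r293 <- ratio_from_erev(ionic_conditions(cs$k_ex, cs$k_in,
      ph_ex = cs$ph_ex, ph_in = 7.4, temperature = 293), cs$e)$value
    r298 <- ratio_from_erev(ionic_conditions(cs$k_ex, cs$k_in,
      ph_ex = cs$ph_ex, ph_in = 7.4, temperature = 298), cs$e)$value
    expect_lt(abs(r298 / r293 - 1), 0.08)
  }
})

test_that("ionic_conditions validates its invariants", {
  expect_error(ionic_conditions(-1, 145, 7.4, 7.4), ">= 0")
  expect_error(ionic_conditions(145, 145, 15, 7.4), "between 0 and 14")
  expect_error(ionic_conditions(145, 145, 7.4, 7.4, temperature = 350),
               "273")
  expect_error(permeability_ratio(-1), "positive")
  expect_error(permeability_ratio(10, gsd = 0.5), "gsd")
})
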