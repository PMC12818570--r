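test_that("gate_open_fraction follows single- and double-site titrations", {
  mut <- cell_model(gate_mode = "mutant-single", mutant_pka = 4.2)
  expect_equal(gate_open_fraction(4.2, mut), 0.5)
  expect_gt(gate_open_fraction(8.5, mut), 0.99)
  expect_lt(gate_open_fraction(1.5, mut), 0.01)
  wt <- cell_model(gate_mode = "wt-double")
  expect_gt(gate_open_fraction(10, wt), 0.99)
  expect_lt(gate_open_fraction(1.5, wt), 0.01)
  # conductance declines with acidification
  ph <- seq(3, 8.5, by = 0.5)
  expect_true(all(diff(gate_open_fraction(ph, wt)) > 0))
  # fixed mode pins the gate open
  expect_equal(gate_open_fraction(c(3, 7), cell_model(gate_mode = "fixed")),
               c(1, 1))
})

test_that("internal pH is conserved without proton pathways", {
  m <- cell_model(p_h_max = 0, weak_acid_permeability = 0,
                  pipette_exchange_rate = 0, gate_mode = "fixed",
                  noise_sigma = 0, temperature = T_REF)
  b <- bath_state(145, 4.7)
  st <- step_state(NULL, -120, m, b, 60)
  expect_equal(unname(st[["ph_in"]]), 7.4, tolerance = 1e-9)
})

test_that("a very large buffer capacity freezes the reversal potential", {
  m <- cell_model(buffer_capacity_in = 1e6, gate_mode = "fixed",
                  pipette_exchange_rate = 0, noise_sigma = 0,
                  temperature = T_REF)
  tc <- run_timecourse(m, test_protocol(), acid_jump_baths(12), n_sweeps = 8)
  post <- tc$e_rev[tc$sweep_time >= 20]
  expect_lt(diff(range(post)), 0.05)
})

test_that("buffered proton content is conserved in a closed two-compartment system", {
  m <- cell_model(gate_mode = "fixed", pipette_exchange_rate = 0,
                  external_volume_pL = 3, buffer_capacity_ex = 20,
                  buffer_capacity_in = 50, noise_sigma = 0,
                  temperature = T_REF)
  b <- bath_state(145, 4.7)
  st0 <- step_state(NULL, 0, m, b, 1e-6)
  st1 <- step_state(st0, -60, m, b, 30)
  content <- function(st) {
    50 * 1 * st[["ph_in"]] + 20 * 3 * st[["ph_ex"]]  # beta * volume * pH
  }
  expect_gt(abs(st1[["ph_in"]] - st0[["ph_in"]]), 0.01)  # erosion happened
  expect_equal(content(st1), content(st0), tolerance = 1e-6)
})

test_that("noiseless GHK ramps reproduce the programmed reversal potential", {
  for (r in c(1e3, 5e4)) {
    m <- cell_model(p_k_max = 2, p_h_max = h_conductance_for_ratio(r, 2),
                    gate_mode = "fixed", buffer_capacity_in = 1e6,
                    pipette_exchange_rate = 0, noise_sigma = 0,
                    temperature = T_REF)
    tc <- run_timecourse(m, test_protocol(), acid_jump_baths(5), n_sweeps = 3,
                         t_start = 10)
    cond <- cond_wt_acid()
    expect_lt(abs(tc$e_rev[3] - erev_from_ratio(cond, r)), 0.1)
  }
})

test_that("reverse-ramp E_rev is left-shifted during the erosion phase", {
  m <- cell_model(noise_sigma = 0, buffer_capacity_in = 20,
                  temperature = T_REF)
  tc <- run_timecourse(m, test_protocol(), acid_jump_baths(12), n_sweeps = 14)
  decay <- which(tc$sweep_time > 40 & !is.na(tc$hysteresis))
  # hysteresis = e_fwd - e_rev > 0 means the reverse ramp is left-shifted
  expect_true(all(tc$hysteresis[decay] > 0))
})

test_that("identical seeds give identical recordings", {
  m <- cell_model(noise_sigma = 5, seed = 123, temperature = T_REF)
  tc1 <- run_timecourse(m, test_protocol(), acid_jump_baths(5), n_sweeps = 3)
  tc2 <- run_timecourse(m, test_protocol(), acid_jump_baths(5), n_sweeps = 3)
  expect_identical(tc1$e_rev, tc2$e_rev)
  m2 <- cell_model(noise_sigma = 5, seed = 124, temperature = T_REF)
  tc3 <- run_timecourse(m2, test_protocol(), acid_jump_baths(5), n_sweeps = 3)
  expect_false(identical(tc1$e_rev, tc3$e_rev))
})

test_that("analytic_tau scales with buffer capacity and conductance", {
  m <- cell_model(gate_mode = "fixed", pipette_exchange_rate = 0,
                  buffer_capacity_in = 50, p_h_max = 10, temperature = T_REF)
  m2 <- cell_model(gate_mode = "fixed", pipette_exchange_rate = 0,
                   buffer_capacity_in = 100, p_h_max = 10, temperature = T_REF)
  m3 <- cell_model(gate_mode = "fixed", pipette_exchange_rate = 0,
                   buffer_capacity_in = 50, p_h_max = 20, temperature = T_REF)
  expect_equal(analytic_tau(m2, 4.7), 2 * analytic_tau(m, 4.7))
  expect_equal(analytic_tau(m3, 4.7), analytic_tau(m, 4.7) / 2)
  expect_error(analytic_tau(cell_model(), 4.7), "exchange")
})

test_that("current clamp matches Nernst and voltage-clamp behavior", {
  # pure-K cell rests at the K+ Nernst potential
  mk <- cell_model(p_h_max = 0, gate_mode = "fixed", noise_sigma = 0,
                   temperature = T_REF)
  cc <- simulate_current_clamp(mk, 2,
    data.frame(time = 0, k_ex_mM = 19, ph_ex = 7.4, solution_id = "a"),
    dt = 1)
  expect_equal(cc$v_mem_mV, rep(nernst_potential(19, 145, 1, T_REF), 3),
               tolerance = 1e-6)
  # acidification depolarizes transiently; peak close to the voltage-clamp
  # E_rev peak of the same model
  mw <- cell_model(noise_sigma = 0, pipette_exchange_rate = 0,
                   temperature = T_REF)
  baths <- acid_jump_baths(10)
  cc2 <- simulate_current_clamp(mw, 240, baths, dt = 1)
  tc <- run_timecourse(mw, test_protocol(), baths, n_sweeps = 13)
  expect_gt(max(cc2$v_mem_mV), 20)
  expect_lt(abs(max(cc2$v_mem_mV) - max(tc$e_rev, na.rm = TRUE)), 2)
  # the depolarization decays again as the gradient erodes
  expect_lt(cc2$v_mem_mV[241], 0.6 * max(cc2$v_mem_mV))
  # with pipette exchange the balance sustains the depolarization instead
  msus <- cell_model(noise_sigma = 0, pipette_exchange_rate = 0.01,
                     temperature = T_REF)
  cc3 <- simulate_current_clamp(msus, 240, baths, dt = 1)
  expect_gt(cc3$v_mem_mV[241], 0.6 * max(cc3$v_mem_mV))
  expect_error(
    simulate_current_clamp(cell_model(p_h_max = 0, p_k_max = 0), 1,
      data.frame(time = 0, k_ex_mM = 145, ph_ex = 7.4, solution_id = "a")),
    "permeability")
})

test_that("peak E_rev is non-decreasing in buffer capacity", {
  peaks <- vapply(c(5, 50, 200), function(beta) {
    m <- cell_model(buffer_capacity_in = beta, noise_sigma = 0,
                    temperature = T_REF)
    tc <- run_timecourse(m, test_protocol(), acid_jump_baths(12),
                         n_sweeps = 12)
    max(tc$e_rev, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("weak-acid loading lowers the peak and accelerates the backshift", {
  base <- cell_model(buffer_capacity_in = 50, noise_sigma = 0,
                     temperature = T_REF)
  loaded <- cell_model(buffer_capacity_in = 50, noise_sigma = 0,
                       weak_acid_permeability = 0.02,
                       weak_acid_total_ex = 50, temperature = T_REF)
  tc_b <- run_timecourse(base, test_protocol(), acid_jump_baths(12),
                         n_sweeps = 14)
  tc_l <- run_timecourse(loaded, test_protocol(), acid_jump_baths(12),
                         n_sweeps = 14)
  expect_lt(max(tc_l$e_rev, na.rm = TRUE), max(tc_b$e_rev, na.rm = TRUE))
  expect_lt(tc_l$e_rev[14], tc_b$e_rev[14])  # faster return toward baseline
})

test_that("step_state flags parameters that push pH out of range", {
  m <- cell_model(buffer_capacity_in = 0.001, compartment_volume_pL = 0.01,
                  gate_mode = "fixed", pipette_exchange_rate = 0,
                  noise_sigma = 0, temperature = T_REF)
  expect_error(step_state(NULL, -120, m, bath_state(145, 2), 300),
               "pH range")
})

test_that("make_fixtures writes a deterministic, complete fixture set", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  f1 <- make_fixtures(d1, seed = 3, n_sweeps = 4)
  f2 <- make_fixtures(d2, seed = 3, n_sweeps = 4)
  expect_true(all(file.exists(f1)))
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_true(all(unlist(man$files) %in% basename(f1)))
  # the ramp fixture round-trips through the reader and analyzer
  sw <- read_sweeps(file.path(d1, "synthetic_wt_ramps.csv"))
  tc <- build_timecourse(sw, attr(sw, "protocol"),
                         events = attr(sw, "events"))
  expect_equal(nrow(tc), 4)
  unlink(c(d1, d2), recursive = TRUE)
})
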