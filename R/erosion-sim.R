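#' Whole-cell biophysical model for pH-gradient erosion
#'
#' Parameterizes a single-compartment whole-cell model in which GHK H+ and
#' K+ fluxes through a pH-gated channel erode the local transmembrane pH
#' gradient against cytosolic buffering, first-order pipette exchange and
#' (optionally) weak-acid loading. The eroding compartment is an effective
#' sub-membrane cytosolic volume; the pipette acts as a first-order pH
#' reservoir. Geometry defaults (20 pF, 1 pL) are calibration constants,
#' not measurements.
#'
#' Permeabilities are specified as conductance equivalents: `p_k_max` is
#' the K+ chord conductance (nS) under symmetric `ref_k_mM`, `p_h_max` the
#' H+ chord conductance (nS) under symmetric pH `ref_ph`; both are
#' converted internally to lumped GHK permeabilities (L/s). The programmed
#' selectivity of the open channel is `model_permeability_ratio(model)`.
#'
#' Gating has two branches with separate kinetics:
#' * K branch: instantaneous (default) acid enhancement from a baseline
#'   fraction `k_base` at alkaline pH toward 1 at acidic pH (midpoint
#'   `gate_pka2`).
#' * H branch: acid activation from baseline `h_base` with midpoint
#'   `h_gate_pka` and a first-order delay `h_gate_delay_tau`, reproducing
#'   the observed temporal uncoupling in which conductance rises before the
#'   reversal potential moves. The midpoint sits below the sensor's
#'   single-site pK_A, reflecting that proton flux requires essentially
#'   complete protonation of the luminal sensor cluster.
#'
#' `gate_mode = "fixed"` pins both branches fully open (useful for clean
#' parameter-recovery fixtures). The pH dependence measured in
#' symmetric-pH SSME titrations is a different observable and is modeled by
#' [gate_open_fraction()].
#'
#' @param capacitance_pF cell capacitance (pF), > 0.
#' @param p_k_max,p_h_max branch conductance equivalents (nS), >= 0.
#' @param ref_k_mM,ref_ph reference conditions defining the conductance
#'   equivalents.
#' @param k_in_mM effective internal (pipette) K+ (mM, Cs-corrected).
#' @param gate_pka1,gate_pka2 titration midpoints; `gate_pka2` also sets the
#'   acid-activation midpoint of the whole-cell gates.
#' @param gate_w weight of the `gate_pka1` site in the wt double titration.
#' @param gate_mode `"wt-double"`, `"mutant-single"` or `"fixed"`.
#' @param mutant_pka single-site midpoint in mutant mode.
#' @param k_base baseline K-branch open fraction at alkaline pH.
#' @param h_base baseline H-branch open fraction at alkaline pH.
#' @param h_gate_pka acid-activation midpoint of the H branch.
#' @param h_gate_delay_tau,k_gate_delay_tau gate relaxation times (s, >= 0;
#'   0 means instantaneous).
#' @param compartment_volume_pL effective cytosolic compartment volume (pL).
#' @param buffer_capacity_in,buffer_capacity_ex buffer capacity beta
#'   (mM per pH unit) of the internal compartment / external layer.
#' @param external_volume_pL external unstirred-layer volume (pL);
#'   `Inf` (default) keeps the external pH clamped by perfusion.
#' @param pipette_exchange_rate first-order exchange rate with the pipette
#'   (1/s).
#' @param pipette_ph pipette pH.
#' @param weak_acid_permeability first-order permeation rate of the neutral
#'   weak-acid form (1/s); 0 disables weak-acid loading.
#' @param weak_acid_total_ex total external weak-acid concentration (mM).
#' @param weak_acid_pka weak-acid pK_A (acetate: 4.76).
#' @param noise_sigma additive Gaussian recording noise SD (pA).
#' @param seed integer seed for the recording noise.
#' @param temperature absolute temperature in K.
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(capacitance_pF = 20,
                       p_k_max = 2, p_h_max = 10,
                       ref_k_mM = 145, ref_ph = 4.7,
                       k_in_mM = 145,
                       gate_pka1 = 4.5, gate_pka2 = 7.0, gate_w = 0.5,
                       gate_mode = c("wt-double", "mutant-single", "fixed"),
                       mutant_pka = 4.2,
                       k_base = 0.25, h_base = 0.01, h_gate_pka = 5.5,
                       h_gate_delay_tau = 10, k_gate_delay_tau = 0,
                       compartment_volume_pL = 1,
                       buffer_capacity_in = 50, buffer_capacity_ex = 50,
                       external_volume_pL = Inf,
                       pipette_exchange_rate = 0.01, pipette_ph = 7.4,
                       weak_acid_permeability = 0, weak_acid_total_ex = 0,
                       weak_acid_pka = 4.76,
                       noise_sigma = 5, seed = 1L,
                       temperature = DEFAULT_TEMPERATURE) {
  gate_mode <- match.arg(gate_mode)
  stopifnot(capacitance_pF > 0, compartment_volume_pL > 0,
            buffer_capacity_in > 0, buffer_capacity_ex > 0,
            p_k_max >= 0, p_h_max >= 0,
            h_gate_delay_tau >= 0, k_gate_delay_tau >= 0,
            k_base >= 0, k_base <= 1, h_base >= 0, h_base <= 1,
            weak_acid_permeability >= 0, weak_acid_total_ex >= 0)
  .check_temperature(temperature)
  m <- list(capacitance_pF = capacitance_pF,
            p_k_max = p_k_max, p_h_max = p_h_max,
            ref_k_mM = ref_k_mM, ref_ph = ref_ph, k_in_mM = k_in_mM,
            gate_pka1 = gate_pka1, gate_pka2 = gate_pka2, gate_w = gate_w,
            gate_mode = gate_mode, mutant_pka = mutant_pka,
            k_base = k_base, h_base = h_base, h_gate_pka = h_gate_pka,
            h_gate_delay_tau = h_gate_delay_tau,
            k_gate_delay_tau = k_gate_delay_tau,
            compartment_volume_pL = compartment_volume_pL,
            buffer_capacity_in = buffer_capacity_in,
            buffer_capacity_ex = buffer_capacity_ex,
            external_volume_pL = external_volume_pL,
            pipette_exchange_rate = pipette_exchange_rate,
            pipette_ph = pipette_ph,
            weak_acid_permeability = weak_acid_permeability,
            weak_acid_total_ex = weak_acid_total_ex,
            weak_acid_pka = weak_acid_pka,
            noise_sigma = noise_sigma, seed = as.integer(seed),
            temperature = temperature)
  # lumped permeabilities (L/s)
  m$p_k <- permeability_from_conductance(p_k_max, .mm_to_molar(ref_k_mM),
                                         temperature = temperature)
  m$p_h <- permeability_from_conductance(p_h_max, .ph_to_molar(ref_ph),
                                         temperature = temperature)
  class(m) <- "cell_model"
  m
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model> g_K = %g nS, g_H = %g nS (P_H/P_K = %.3g), gates '%s', beta_in = %g mM/pH, V = %g pL\n",
    x$p_k_max, x$p_h_max, model_permeability_ratio(x), x$gate_mode,
    x$buffer_capacity_in, x$compartment_volume_pL))
  invisible(x)
}

#' Programmed open-channel permeability ratio of a cell model
#'
#' @param model a [cell_model()].
#' @return P_H/P_K of the fully open channel (dimensionless).
#' @export
model_permeability_ratio <- function(model) model$p_h / model$p_k

#' H+ conductance equivalent programming a target permeability ratio
#'
#' Returns the `p_h_max` (nS) that makes a [cell_model()] with K-branch
#' conductance `p_k_max` have an open-channel P_H/P_K equal to `ratio`.
#'
#' @param ratio target P_H/P_K.
#' @param p_k_max K-branch conductance equivalent (nS).
#' @param ref_k_mM,ref_ph reference conditions (must match the model's).
#' @return `p_h_max` in nS.
#' @export
h_conductance_for_ratio <- function(ratio, p_k_max, ref_k_mM = 145,
                                    ref_ph = 4.7) {
  ratio * p_k_max * .ph_to_molar(ref_ph) / .mm_to_molar(ref_k_mM)
}

#' Bath state
#'
#' @param k_ex_mM effective external K+ (mM, Cs-corrected).
#' @param ph_ex external pH.
#' @param solution_id label.
#' @return An object of class `bath_state`.
#' @export
bath_state <- function(k_ex_mM, ph_ex, solution_id = "std") {
  .check_ph(ph_ex, "ph_ex")
  structure(list(k_ex_mM = k_ex_mM, ph_ex = ph_ex, solution_id = solution_id),
            class = "bath_state")
}

#' Equilibrium open fraction from a symmetric-pH titration
#'
#' The pH dependence of channel flux measured under symmetric pH (as in
#' SSME K+-jump titrations): conductance declines with acidification.
#' Wild-type behavior is a two-site titration
#' `f(pH) = w * s(pH; pKa1) + (1 - w) * s(pH; pKa2)` with
#' `s(pH; pKa) = 1/(1 + 10^(pKa - pH))`; the mutant lacking the titratable
#' histidine shows a single site at `mutant_pka`.
#'
#' @param ph pH value(s).
#' @param model a [cell_model()] supplying pK_A values, weight and mode.
#' @param which `"K"` or `"H"` branch (same titration form for both).
#' @return Open fraction in `[0, 1]` (vectorized over `ph`).
#' @export
gate_open_fraction <- function(ph, model, which = c("K", "H")) {
  which <- match.arg(which)
  sig <- function(ph, pka) 1 / (1 + 10^(pka - ph))
  switch(model$gate_mode,
    "fixed" = rep(1, length(ph)),
    "mutant-single" = sig(ph, model$mutant_pka),
    "wt-double" = model$gate_w * sig(ph, model$gate_pka1) +
      (1 - model$gate_w) * sig(ph, model$gate_pka2))
}

# Acid-activation targets driving the whole-cell gates (direction opposite
# to the symmetric-pH titration; see the methods vignette).
.acid_sigma <- function(ph, pka) 1 / (1 + 10^(ph - pka))

.h_gate_target <- function(ph_ex, model) {
  if (model$gate_mode == "fixed") return(1)
  model$h_base + (1 - model$h_base) * .acid_sigma(ph_ex, model$h_gate_pka)
}

.k_gate_target <- function(ph_ex, model) {
  if (model$gate_mode == "fixed") return(1)
  model$k_base + (1 - model$k_base) * .acid_sigma(ph_ex, model$gate_pka2)
}

# neutral weak-acid concentration (mol/L) given total (mol/L) and pH
.ha_conc <- function(total, ph, pka) total / (1 + 10^(ph - pka))

# Instantaneous membrane currents (A). state: named numeric
# (ph_in, a_h, a_k, wa_in, ph_ex). bath supplies k_ex; k_in from model.
.currents <- function(state, v, model, bath) {
  h_in <- .ph_to_molar(state[["ph_in"]])
  h_ex <- .ph_to_molar(state[["ph_ex"]])
  k_in <- .mm_to_molar(model$k_in_mM)
  k_ex <- .mm_to_molar(bath$k_ex_mM)
  i_h <- ghk_current(model$p_h * state[["a_h"]], 1L, h_in, h_ex, v,
                     model$temperature)
  i_k <- ghk_current(model$p_k * state[["a_k"]], 1L, k_in, k_ex, v,
                     model$temperature)
  c(i_h = i_h, i_k = i_k)
}

# Time derivative of the model state at voltage v (mV).
.state_deriv <- function(state, v, model, bath) {
  cur <- .currents(state, v, model, bath)
  v_in <- model$compartment_volume_pL * 1e-12      # L
  beta_in <- .mm_to_molar(model$buffer_capacity_in) # mol/L per pH
  # outward (positive) H+ current removes internal protons -> pH_in rises
  dph_in <- cur[["i_h"]] / (.FARADAY * v_in * beta_in) +
    model$pipette_exchange_rate * (model$pipette_ph - state[["ph_in"]])
  dwa <- 0
  if (model$weak_acid_permeability > 0) {
    ha_ex <- .ha_conc(.mm_to_molar(model$weak_acid_total_ex),
                      state[["ph_ex"]], model$weak_acid_pka)
    ha_in <- .ha_conc(state[["wa_in"]], state[["ph_in"]], model$weak_acid_pka)
    j <- model$weak_acid_permeability * (ha_ex - ha_in)  # mol/L/s into cell
    dwa <- j
    f_dep <- 1 - 1 / (1 + 10^(state[["ph_in"]] - model$weak_acid_pka))
    dph_in <- dph_in - j * f_dep / beta_in
  }
  dph_ex <- 0
  if (is.finite(model$external_volume_pL)) {
    v_ex <- model$external_volume_pL * 1e-12
    beta_ex <- .mm_to_molar(model$buffer_capacity_ex)
    # outward H+ current adds protons to the external layer -> pH_ex falls
    dph_ex <- -cur[["i_h"]] / (.FARADAY * v_ex * beta_ex)
  }
  da_h <- if (model$h_gate_delay_tau > 0) {
    (.h_gate_target(state[["ph_ex"]], model) - state[["a_h"]]) /
      model$h_gate_delay_tau
  } else 0
  da_k <- if (model$k_gate_delay_tau > 0) {
    (.k_gate_target(state[["ph_ex"]], model) - state[["a_k"]]) /
      model$k_gate_delay_tau
  } else 0
  c(ph_in = unname(dph_in), a_h = da_h, a_k = da_k,
    wa_in = unname(dwa), ph_ex = unname(dph_ex))
}

# Initial state equilibrated to a bath.
.init_state <- function(model, bath, ph_in = NULL) {
  c(ph_in = if (is.null(ph_in)) model$pipette_ph else ph_in,
    a_h = .h_gate_target(bath$ph_ex, model),
    a_k = .k_gate_target(bath$ph_ex, model),
    wa_in = 0, ph_ex = bath$ph_ex)
}

# Pin instantaneous gates to their targets (called after bath switches).
.snap_gates <- function(state, model) {
  if (model$h_gate_delay_tau == 0) {
    state[["a_h"]] <- .h_gate_target(state[["ph_ex"]], model)
  }
  if (model$k_gate_delay_tau == 0) {
    state[["a_k"]] <- .k_gate_target(state[["ph_ex"]], model)
  }
  state
}

.check_state <- function(state) {
  if (!is.finite(state[["ph_in"]]) || state[["ph_in"]] <= 0 ||
      state[["ph_in"]] >= 14 || state[["ph_ex"]] <= 0 ||
      state[["ph_ex"]] >= 14) {
    stop(paste0(
      "integration left the physical pH range (ph_in = ",
      signif(state[["ph_in"]], 4), ", ph_ex = ", signif(state[["ph_ex"]], 4),
      "); check buffer_capacity_in / compartment_volume_pL / permeabilities"),
      call. = FALSE)
  }
  invisible(state)
}

#' Advance the model state at a fixed voltage
#'
#' Integrates the erosion dynamics (local internal pH, gate activations,
#' internal weak-acid pool, optional external-layer pH) for `dt` seconds at
#' the clamped membrane potential `v`, using the stiff-capable `lsoda`
#' integrator.
#'
#' @param state named state vector as produced by
#'   `attr(simulate_voltage_clamp(...), "final_state")` or internally; pass
#'   `NULL` to start from equilibrium in `bath`.
#' @param v clamped membrane potential (mV).
#' @param model a [cell_model()].
#' @param bath a [bath_state()].
#' @param dt duration (s).
#' @return The advanced named state vector.
#' @export
step_state <- function(state, v, model, bath, dt) {
  if (is.null(state)) state <- .init_state(model, bath)
  out <- .integrate_state(state, model, bath, function(t) v, 0, dt,
                          n_out = 2L)
  st <- out$state
  .check_state(st)
  st
}

# Core integrator: advance `state` from t0 to t1 with voltage v_fun(t) (mV).
# Returns list(state = final, traj = data.frame(time, ph_in, a_h, a_k, ph_ex))
.integrate_state <- function(state, model, bath, v_fun, t0, t1,
                             n_out = 2L) {
  if (t1 <= t0) return(list(state = state, traj = NULL))
  times <- seq(t0, t1, length.out = max(2L, n_out))
  deriv <- function(t, y, parms) {
    list(.state_deriv(y, v_fun(t), model, bath))
  }
  sol <- deSolve::ode(y = state, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  traj <- as.data.frame(sol)
  final <- unlist(traj[nrow(traj), -1])
  list(state = final, traj = traj)
}

#' Simulate a voltage-clamp ramp experiment
#'
#' Integrates the erosion model along a repeated symmetric ramp protocol
#' with a bath schedule, emitting one [new_sweep()] per repetition in the
#' format consumed by [build_timecourse()]. Between sweeps the cell is
#' clamped at `v_hold`; the clamp is ideal (no series resistance). Recording
#' noise is additive Gaussian on the current, controlled by `model$noise_sigma`
#' and `model$seed` (the only randomness; the dynamics are deterministic).
#'
#' @param model a [cell_model()].
#' @param protocol a [ramp_protocol()] (its `inter_sweep_interval` sets the
#'   sweep spacing).
#' @param baths data.frame schedule with columns `time` (s, experiment
#'   clock; first row at or before 0), `k_ex_mM`, `ph_ex`, `solution_id`.
#' @param n_sweeps number of sweeps to simulate.
#' @param v_hold holding potential between sweeps (mV).
#' @param t_start experiment-clock time of the first sweep (s).
#' @param state optional initial state (default: equilibrium in the first
#'   bath with internal pH at the pipette pH).
#' @return list of [new_sweep()] objects; attributes `events` (bath
#'   switches) and `final_state`.
#' @export
simulate_voltage_clamp <- function(model, protocol, baths, n_sweeps,
                                   v_hold = 0, t_start = 0, state = NULL) {
  stopifnot(inherits(model, "cell_model"), inherits(protocol, "ramp_protocol"),
            all(c("time", "k_ex_mM", "ph_ex", "solution_id") %in% names(baths)),
            n_sweeps >= 1)
  baths <- baths[order(baths$time), , drop = FALSE]
  set.seed(model$seed)
  bath_at <- function(t) {
    k <- findInterval(t + 1e-9, baths$time)
    if (k < 1) k <- 1
    bath_state(baths$k_ex_mM[k], baths$ph_ex[k], baths$solution_id[k])
  }
  cur_bath <- bath_at(min(0, t_start))
  if (is.null(state)) state <- .init_state(model, cur_bath)
  state <- .snap_gates(state, model)

  vcmd <- protocol_voltage(protocol)
  sweep_dur <- max(vcmd$t_s) + 1 / protocol$sample_rate
  interval <- protocol$inter_sweep_interval
  sweep_starts <- t_start + (seq_len(n_sweeps) - 1) * interval

  # advance through holds, splitting at bath-switch times
  advance_hold <- function(state, t0, t1) {
    if (t1 <= t0) return(state)
    cuts <- sort(unique(c(t0, baths$time[baths$time > t0 & baths$time < t1], t1)))
    for (k in seq_len(length(cuts) - 1)) {
      b <- bath_at(cuts[k])
      st <- state
      st[["ph_ex"]] <- b$ph_ex  # perfusion clamps the bath pH on switch
      st <- .snap_gates(st, model)
      res <- .integrate_state(st, model, b, function(t) v_hold,
                              cuts[k], cuts[k + 1], n_out = 2L)
      state <- res$state
      .check_state(state)
    }
    state
  }

  sweeps <- vector("list", n_sweeps)
  t_now <- min(0, t_start)
  for (s in seq_len(n_sweeps)) {
    state <- advance_hold(state, t_now, sweep_starts[s])
    b <- bath_at(sweep_starts[s])
    state[["ph_ex"]] <- b$ph_ex
    state <- .snap_gates(state, model)
    # integrate through the sweep on a 1 ms state grid, then evaluate
    # currents on the full 20 kHz command waveform from interpolated state
    v_of_t <- function(t) {
      approx(vcmd$t_s, vcmd$v_mV, xout = t - sweep_starts[s], rule = 2)$y
    }
    res <- .integrate_state(state, model, b,
                            v_of_t, sweep_starts[s],
                            sweep_starts[s] + sweep_dur,
                            n_out = max(8L, ceiling(sweep_dur / 5e-3)))
    traj <- res$traj
    state <- res$state
    .check_state(state)
    tt <- sweep_starts[s] + vcmd$t_s
    st_i <- function(col) approx(traj$time, traj[[col]], xout = tt, rule = 2)$y
    h_in <- .ph_to_molar(st_i("ph_in"))
    h_ex <- .ph_to_molar(st_i("ph_ex"))
    i_h <- ghk_current(model$p_h, 1L, h_in, h_ex, vcmd$v_mV,
                       model$temperature) * st_i("a_h")
    i_k <- ghk_current(model$p_k, 1L, .mm_to_molar(model$k_in_mM),
                       .mm_to_molar(b$k_ex_mM), vcmd$v_mV,
                       model$temperature) * st_i("a_k")
    i_pA <- (i_h + i_k) * 1e12
    if (model$noise_sigma > 0) {
      i_pA <- i_pA + rnorm(length(i_pA), 0, model$noise_sigma)
    }
    sweeps[[s]] <- new_sweep(vcmd$t_s, vcmd$v_mV, i_pA,
                             capacitance = model$capacitance_pF,
                             sweep_time = sweep_starts[s],
                             solution_id = b$solution_id)
    t_now <- sweep_starts[s] + sweep_dur
  }
  ev <- data.frame(time = baths$time, label = baths$solution_id,
                   stringsAsFactors = FALSE)
  attr(sweeps, "events") <- ev
  attr(sweeps, "final_state") <- state
  sweeps
}

#' Simulate a current-clamp (free-running membrane voltage) recording
#'
#' At zero injected current the membrane settles at the zero-current
#' potential of the summed GHK fluxes; at each step this voltage is found by
#' root bracketing between the K+ and H+ Nernst potentials (widened by 20
#' mV) and the erosion state is then advanced at that voltage.
#'
#' @param model a [cell_model()].
#' @param duration total simulated time (s).
#' @param baths bath schedule as in [simulate_voltage_clamp()].
#' @param dt reporting/integration step (s).
#' @param state optional initial state.
#' @return data.frame with `t_s`, `v_mem_mV`, `ph_in`, `ph_ex`, `a_h`, `a_k`.
#' @export
simulate_current_clamp <- function(model, duration, baths, dt = 0.1,
                                   state = NULL) {
  stopifnot(inherits(model, "cell_model"))
  if (model$p_h <= 0 && model$p_k <= 0) {
    stop("at least one permeability must be non-zero", call. = FALSE)
  }
  baths <- baths[order(baths$time), , drop = FALSE]
  bath_at <- function(t) {
    k <- max(1, findInterval(t + 1e-9, baths$time))
    bath_state(baths$k_ex_mM[k], baths$ph_ex[k], baths$solution_id[k])
  }
  times <- seq(0, duration, by = dt)
  b <- bath_at(0)
  if (is.null(state)) state <- .init_state(model, b)
  state <- .snap_gates(state, model)
  out <- data.frame(t_s = times, v_mem_mV = NA_real_, ph_in = NA_real_,
                    ph_ex = NA_real_, a_h = NA_real_, a_k = NA_real_)
  for (k in seq_along(times)) {
    b <- bath_at(times[k])
    state[["ph_ex"]] <- b$ph_ex
    state <- .snap_gates(state, model)
    e_k <- nernst_potential(b$k_ex_mM, model$k_in_mM,
                            temperature = model$temperature)
    e_h <- nernst_potential(.ph_to_molar(state[["ph_ex"]]),
                            .ph_to_molar(state[["ph_in"]]),
                            temperature = model$temperature)
    lo <- min(e_k, e_h) - 20; hi <- max(e_k, e_h) + 20
    f <- function(v) sum(.currents(state, v, model, b))
    v0 <- tryCatch(uniroot(f, c(lo, hi), tol = 1e-10)$root,
                   error = function(e) {
                     stop("zero-current bracketing failed in [",
                          signif(lo, 4), ", ", signif(hi, 4), "] mV",
                          call. = FALSE)
                   })
    out$v_mem_mV[k] <- v0
    out$ph_in[k] <- state[["ph_in"]]; out$ph_ex[k] <- state[["ph_ex"]]
    out$a_h[k] <- state[["a_h"]]; out$a_k[k] <- state[["a_k"]]
    if (k < length(times)) {
      res <- .integrate_state(state, model, b, function(t) v0,
                              times[k], times[k + 1], n_out = 2L)
      state <- res$state
      .check_state(state)
    }
  }
  out
}

#' Conditioning-voltage protocol
#'
#' Reproduces the conditioning experiment: after `pre_time` seconds of
#' erosion at `v_pre` in the acidic bath, the cell is clamped for
#' `hold_time` seconds to each conditioning voltage in `v_holds` (each from
#' the same post-erosion state), followed by one fast ramp from which E_rev
#' is extracted.
#'
#' @param model a [cell_model()].
#' @param bath the acidic [bath_state()].
#' @param v_holds conditioning voltages (mV).
#' @param pre_time erosion time before conditioning (s).
#' @param hold_time conditioning duration (s).
#' @param v_pre holding potential during the erosion phase (mV).
#' @param protocol ramp protocol for the test ramp.
#' @return data.frame with `v_hold` and `e_rev` (mV).
#' @export
simulate_conditioning <- function(model, bath, v_holds,
                                  pre_time = 90, hold_time = 20, v_pre = 0,
                                  protocol = ramp_protocol()) {
  st0 <- .snap_gates(.init_state(model, bath), model)
  st0 <- step_state(st0, v_pre, model, bath, pre_time)
  res <- lapply(seq_along(v_holds), function(i) {
    vh <- v_holds[i]
    st <- step_state(st0, vh, model, bath, hold_time)
    model$seed <- model$seed + i  # independent recording noise per hold
    sweeps <- simulate_voltage_clamp(model, protocol,
      baths = data.frame(time = 0, k_ex_mM = bath$k_ex_mM,
                         ph_ex = bath$ph_ex, solution_id = bath$solution_id),
      n_sweeps = 1, v_hold = vh, t_start = 0, state = st)
    tc <- build_timecourse(sweeps, protocol)
    data.frame(v_hold = vh, e_rev = tc$e_rev[1])
  })
  do.call(rbind, res)
}

#' Linearized erosion time constant
#'
#' Closed-form small-signal time constant of the reversal-potential
#' backshift at a 0 mV holding potential with pipette exchange and weak-acid
#' loading switched off. Linearizing the proton flux around the fully
#' eroded state (internal pH equal to external pH) gives
#' \deqn{\tau = \frac{F^2 v \beta}{R T \ln 10\; g_H}
#'        = \frac{v\,\beta}{P_H\, a_H\, 10^{-pH_{ex}} \ln 10}}
#' where v is the compartment volume (L), beta the internal buffer capacity
#' (mol/L/pH), and g_H the H+ chord conductance under symmetric pH_ex
#' (lumped permeability P_H times equilibrium gate fraction a_H). Serves as
#' the analytic oracle for [fit_erev_decay()] on simulator output in the
#' small-gradient limit.
#'
#' @param model a [cell_model()] (weak acid off, pipette exchange off).
#' @param ph_ex external pH of the erosion condition.
#' @return tau in seconds.
#' @export
analytic_tau <- function(model, ph_ex) {
  if (model$weak_acid_permeability > 0 || model$pipette_exchange_rate > 0) {
    stop("analytic_tau assumes weak acid and pipette exchange are off",
         call. = FALSE)
  }
  v <- model$compartment_volume_pL * 1e-12
  beta <- .mm_to_molar(model$buffer_capacity_in)
  a_h <- .h_gate_target(ph_ex, model)
  g_h <- model$p_h * a_h * .ph_to_molar(ph_ex)   # P a H_ex (mol/s units folded)
  v * beta / (g_h * log(10))
}

#' Write a deterministic set of synthetic fixture files
#'
#' Generates small, seeded CSV fixtures for every analysis module: a
#' voltage-clamp ramp recording (sweeps CSV plus YAML sidecar), a
#' current-clamp trace, an SSME dataset and a salt-bridge distance table,
#' together with a JSON manifest recording the generating parameters. All
#' files are synthetic; identical seeds give identical files.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param n_sweeps sweeps in the ramp fixture.
#' @return (invisibly) character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 1L, n_sweeps = 12) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proto <- ramp_protocol(sample_rate = 2000, inter_sweep_interval = 10)
  model <- cell_model(noise_sigma = 2, seed = seed)
  baths <- data.frame(time = c(-20, 5),
                      k_ex_mM = c(145, 145), ph_ex = c(7.4, 4.7),
                      solution_id = c("pH7.4", "pH4.7"))
  sweeps <- simulate_voltage_clamp(model, proto, baths, n_sweeps = n_sweeps,
                                   t_start = 0)
  f_sweeps <- file.path(dir, "synthetic_wt_ramps.csv")
  f_meta <- file.path(dir, "synthetic_wt_ramps.yaml")
  write_sweeps(sweeps, f_sweeps, f_meta, protocol = proto,
               events = attr(sweeps, "events"))
  cc <- simulate_current_clamp(cell_model(noise_sigma = 0, seed = seed),
                               duration = 60, baths = baths, dt = 0.5)
  f_cc <- file.path(dir, "synthetic_wt_current_clamp.csv")
  write.csv(cc, f_cc, row.names = FALSE)
  ssme <- generate_ssme_dataset(ssme_params(), seed = seed)
  f_ssme <- file.path(dir, "synthetic_ssme.csv")
  write.csv(ssme$traces, f_ssme, row.names = FALSE)
  ds <- generate_distance_series(duration_ns = 200, dt_ns = 1, seed = seed)
  f_sb <- file.path(dir, "synthetic_saltbridge.csv")
  write.csv(as.data.frame(ds), f_sb, row.names = FALSE)
  files <- c(f_sweeps, f_meta, f_cc, f_ssme, f_sb)
  manifest <- list(
    seed = seed,
    files = basename(files),
    ramp = list(n_sweeps = n_sweeps, sample_rate = proto$sample_rate,
                model = model[c("p_k_max", "p_h_max", "buffer_capacity_in",
                                "gate_mode", "noise_sigma")]),
    note = "all files are synthetic, generated by ghksel::make_fixtures")
  f_man <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, f_man))
}
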