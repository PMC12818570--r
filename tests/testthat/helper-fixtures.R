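# Shared fixtures. Simulations in tests use a reduced sampling rate (2 kHz)
# to keep runtimes small; the feature extraction is rate-agnostic.

T_REF <- 295  # K; benchmark evaluations use this temperature

cond_wt_acid <- function() {
  ionic_conditions(145, 145, ph_ex = 4.7, ph_in = 7.4, temperature = T_REF)
}

test_protocol <- function(interval = 10, rate = 2000) {
  ramp_protocol(sample_rate = rate, inter_sweep_interval = interval)
}

# bath schedule: neutral then acid (or other pH) from `t_switch`
acid_jump_baths <- function(t_switch, ph_to = 4.7, k_ex = 145) {
  data.frame(time = c(-20, t_switch), k_ex_mM = k_ex,
             ph_ex = c(7.4, ph_to),
             solution_id = c("pH7.4", sprintf("pH%.1f", ph_to)))
}

# a noiseless ohmic sweep: I = g * (V - e0), following `protocol` timing
ohmic_sweep <- function(g_ns = 10, e0 = 0, protocol = test_protocol(),
                        sweep_time = 0, capacitance = 20, ljp = 0) {
  vc <- protocol_voltage(protocol)
  new_sweep(vc$t_s, vc$v_mV, g_ns * (vc$v_mV - e0),
            capacitance = capacitance, sweep_time = sweep_time,
            ljp_offset = ljp)
}

run_timecourse <- function(model, protocol, baths, n_sweeps, t_start = 0,
                           ...) {
  sw <- simulate_voltage_clamp(model, protocol, baths, n_sweeps = n_sweeps,
                               t_start = t_start, ...)
  build_timecourse(sw, protocol, events = attr(sw, "events"))
}
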