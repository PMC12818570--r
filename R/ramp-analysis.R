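#' Symmetric voltage-ramp protocol
#'
#' The standard protocol: hold at `v_start` (+120 mV) for `hold_pre` ms,
#' ramp to `v_end` (-120 mV) over `ramp_down` ms, hold for `hold_mid` ms,
#' then ramp back over `ramp_up` ms. Both the forward and the reverse ramp
#' are analyzed and their reversal potentials averaged.
#'
#' @param v_start,v_end start/end voltage in mV.
#' @param hold_pre,ramp_down,hold_mid,ramp_up segment durations in ms.
#' @param sample_rate sampling rate in Hz.
#' @param inter_sweep_interval seconds between sweep starts (10 s standard,
#'   1 s for high-time-resolution protocols).
#' @return An object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(v_start = 120, v_end = -120,
                          hold_pre = 25, ramp_down = 150,
                          hold_mid = 25, ramp_up = 150,
                          sample_rate = 20000,
                          inter_sweep_interval = 10) {
  durs <- c(hold_pre = hold_pre, ramp_down = ramp_down,
            hold_mid = hold_mid, ramp_up = ramp_up)
  if (any(durs <= 0)) stop("all durations must be positive", call. = FALSE)
  if (sample_rate <= 0) stop("`sample_rate` must be positive", call. = FALSE)
  structure(list(v_start = v_start, v_end = v_end,
                 hold_pre = hold_pre, ramp_down = ramp_down,
                 hold_mid = hold_mid, ramp_up = ramp_up,
                 sample_rate = sample_rate,
                 inter_sweep_interval = inter_sweep_interval),
            class = "ramp_protocol")
}

# per-segment sample counts (hold_pre, ramp_down, hold_mid, ramp_up)
.protocol_samples <- function(protocol) {
  fs <- protocol$sample_rate
  round(c(protocol$hold_pre, protocol$ramp_down,
          protocol$hold_mid, protocol$ramp_up) / 1000 * fs)
}

#' Command-voltage waveform of a ramp protocol
#'
#' @param protocol a [ramp_protocol()].
#' @return data.frame with `t_s` and `v_mV` at the protocol sample rate.
#' @export
protocol_voltage <- function(protocol) {
  n <- .protocol_samples(protocol)
  fs <- protocol$sample_rate
  v <- c(rep(protocol$v_start, n[1]),
         seq(protocol$v_start, protocol$v_end, length.out = n[2]),
         rep(protocol$v_end, n[3]),
         seq(protocol$v_end, protocol$v_start, length.out = n[4]))
  data.frame(t_s = (seq_along(v) - 1) / fs, v_mV = v)
}

#' One voltage-ramp sweep
#'
#' @param time time within the sweep (s), strictly increasing.
#' @param voltage command voltage (mV).
#' @param current recorded current (pA).
#' @param capacitance cell capacitance (pF), > 0.
#' @param sweep_time experiment-clock time of the sweep start (s).
#' @param solution_id label of the bath solution during this sweep.
#' @param ljp_offset liquid-junction-potential offset (mV) to subtract from
#'   all voltages before analysis (user-supplied; its computation is
#'   upstream of this package).
#' @return An object of class `sweep`.
#' @export
new_sweep <- function(time, voltage, current, capacitance,
                      sweep_time = 0, solution_id = "std", ljp_offset = 0) {
  n <- length(time)
  if (n < 4 || length(voltage) != n || length(current) != n) {
    stop("time/voltage/current must have equal length >= 4", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing", call. = FALSE)
  if (!is.finite(capacitance) || capacitance <= 0) {
    stop("`capacitance` must be positive", call. = FALSE)
  }
  structure(list(time = time, voltage = voltage, current = current,
                 capacitance = capacitance, sweep_time = sweep_time,
                 solution_id = solution_id, ljp_offset = ljp_offset),
            class = "sweep")
}

#' Split a sweep into forward and reverse ramp segments
#'
#' Returns the two monotone-voltage portions of a symmetric ramp sweep
#' (forward: `v_start` to `v_end`; reverse: back), excluding the hold
#' plateaus. A sample-count jitter of +/-1 per segment is tolerated and
#' trimmed symmetrically.
#'
#' @param sweep a [new_sweep()] object.
#' @param protocol the [ramp_protocol()] the sweep was acquired with.
#' @return list with elements `forward` and `reverse`, each a data.frame
#'   with columns `t_s`, `v_mV`, `i_pA`.
#' @export
split_ramp_segments <- function(sweep, protocol) {
  stopifnot(inherits(sweep, "sweep"), inherits(protocol, "ramp_protocol"))
  n_seg <- .protocol_samples(protocol)
  n_tot <- sum(n_seg)
  n <- length(sweep$time)
  if (abs(n - n_tot) > 2L) {
    stop(sprintf("sweep has %d samples but protocol implies %d (+/-2)", n, n_tot),
         call. = FALSE)
  }
  # trim/pad jitter symmetrically at the end
  take <- function(from, len) {
    idx <- seq.int(from, length.out = len)
    idx <- idx[idx <= n]
    data.frame(t_s = sweep$time[idx], v_mV = sweep$voltage[idx],
               i_pA = sweep$current[idx])
  }
  fwd <- take(n_seg[1] + 1L, n_seg[2])
  rev_start <- n_seg[1] + n_seg[2] + n_seg[3] + 1L
  if (rev_start + 3L > n) {
    stop("sweep is missing the reverse ramp segment", call. = FALSE)
  }
  rev <- take(rev_start, min(n_seg[4], n - rev_start + 1L))
  if (nrow(rev) < n_seg[4] - 1L) {
    stop("reverse ramp segment is truncated beyond tolerance", call. = FALSE)
  }
  list(forward = fwd, reverse = rev)
}

#' Reversal potential of one ramp segment
#'
#' Median-smooths the current (default width 11 samples, robust to
#' Bessel-filtered recording noise), locates sign changes, and returns the
#' zero-current crossing by linear interpolation between the bracketing
#' samples. When several crossings survive smoothing, the crossing flanked
#' by the longest monotone sign runs wins; remaining ties are broken by
#' proximity to `prev_erev` (e.g. the previous sweep's value), then by the
#' earliest crossing.
#'
#' @param segment data.frame with columns `v_mV` and `i_pA` (one ramp).
#' @param smooth_width odd median-filter width in samples (1 = no smoothing).
#' @param prev_erev optional previous reversal potential (mV) for
#'   tie-breaking.
#' @return Reversal potential in mV, or `NA` with attribute
#'   `flag = "NoReversal"` if the current does not change sign.
#' @export
extract_reversal <- function(segment, smooth_width = 11, prev_erev = NULL) {
  v <- segment$v_mV; i <- segment$i_pA
  if (length(v) < 4) stop("segment too short", call. = FALSE)
  w <- min(smooth_width, length(i) - (1 - length(i) %% 2))
  ism <- if (w >= 3) as.numeric(runmed(i, w)) else i
  s <- sign(ism)
  s[s == 0] <- 1e-12  # treat exact zeros as crossings via neighbors
  cross <- which(s[-1] * s[-length(s)] < 0)
  # exact zero samples count as crossings too
  zero_idx <- which(ism == 0)
  if (length(cross) == 0 && length(zero_idx) == 0) {
    out <- NA_real_
    attr(out, "flag") <- "NoReversal"
    return(out)
  }
  if (length(cross) == 0) {
    return(v[zero_idx[1]])
  }
  if (length(cross) > 1) {
    # run lengths of the smoothed sign sequence
    r <- rle(sign(ism))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    score <- vapply(cross, function(k) {
      j <- findInterval(k, starts)           # run containing sample k
      min(r$lengths[j], r$lengths[min(j + 1L, length(r$lengths))])
    }, numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1 && !is.null(prev_erev)) {
      cand_v <- v[cross[best]]
      best <- best[which.min(abs(cand_v - prev_erev))]
    } else {
      best <- best[1]
    }
    cross <- cross[best]
  }
  k <- cross[1]
  # linear interpolation between bracketing smoothed samples
  i0 <- ism[k]; i1 <- ism[k + 1]
  v[k] + (0 - i0) / (i1 - i0) * (v[k + 1] - v[k])
}

#' Average forward- and reverse-ramp reversal potentials
#'
#' The reverse ramp's E_rev is typically left-shifted by a few mV relative
#' to the forward ramp's, because the ramp-evoked proton influx itself
#' erodes the pH gradient slightly. Reported E_rev values therefore average
#' the two; the difference is kept as a hysteresis quality metric.
#'
#' @param e_fwd,e_rev forward/reverse reversal potential (mV); either may be
#'   `NA`.
#' @return list with `e_rev` (mean, or the surviving value, or `NA`),
#'   `hysteresis` (e_fwd - e_rev, `NA` when either is missing) and `flags`
#'   (character vector, possibly empty; "OneRampOnly" / "NoReversal").
#' @export
average_fwd_rev <- function(e_fwd, e_rev) {
  f <- c()
  if (is.na(e_fwd) && is.na(e_rev)) {
    return(list(e_rev = NA_real_, hysteresis = NA_real_, flags = "NoReversal"))
  }
  if (is.na(e_fwd) || is.na(e_rev)) {
    return(list(e_rev = if (is.na(e_fwd)) e_rev else e_fwd,
                hysteresis = NA_real_, flags = "OneRampOnly"))
  }
  list(e_rev = (e_fwd + e_rev) / 2, hysteresis = e_fwd - e_rev, flags = f)
}

#' Chord conductance at a test voltage
#'
#' G = I(V_test) / (V_test - E_rev), with I(V_test) the mean current over a
#' small voltage window (default +/-1 mV) around the test voltage on the
#' ramp. With current in pA and voltage in mV the result is in nS. A config
#' switch `denominator = "v"` divides by V_test instead (non-chord
#' convention, for comparison only).
#'
#' @param segment data.frame with `v_mV`, `i_pA`.
#' @param e_rev reversal potential in mV (must differ from `at_voltage`).
#' @param at_voltage test voltage in mV, within the segment's range.
#' @param window full voltage window width in mV (default 2).
#' @param denominator `"driving_force"` (default) or `"v"`.
#' @return Conductance in nS.
#' @export
chord_conductance <- function(segment, e_rev, at_voltage, window = 2,
                              denominator = c("driving_force", "v")) {
  denominator <- match.arg(denominator)
  v <- segment$v_mV; i <- segment$i_pA
  if (at_voltage < min(v) - 1e-9 || at_voltage > max(v) + 1e-9) {
    stop("`at_voltage` outside the segment's voltage range", call. = FALSE)
  }
  if (denominator == "driving_force" &&
      abs(at_voltage - e_rev) <= window / 2) {
    stop("e_rev equals the test voltage: chord conductance is singular",
         call. = FALSE)
  }
  sel <- abs(v - at_voltage) <= window / 2
  if (!any(sel)) sel <- which.min(abs(v - at_voltage))
  i_at <- mean(i[sel])
  v_at <- mean(v[sel])  # actual window-mean voltage (exact for linear I/V)
  den <- if (denominator == "v") v_at else v_at - e_rev
  i_at / den
}

#' Current density
#'
#' @param current current in pA.
#' @param capacitance cell capacitance in pF (> 0).
#' @return Current density in pA/pF.
#' @export
current_density <- function(current, capacitance) {
  if (any(capacitance <= 0)) stop("`capacitance` must be positive", call. = FALSE)
  current / capacitance
}

#' Per-sweep ramp features
#'
#' Extracts E_rev (forward/reverse averaged), chord conductances and current
#' densities at the protocol's extreme voltages from one sweep. The sweep's
#' LJP offset is subtracted from all voltages first.
#'
#' @param sweep a [new_sweep()] object.
#' @param protocol the acquisition [ramp_protocol()].
#' @param prev_erev previous sweep's E_rev for crossing tie-breaks.
#' @return One-row data.frame (class `ramp_features`).
#' @export
ramp_features <- function(sweep, protocol, prev_erev = NULL) {
  sw <- sweep
  sw$voltage <- sw$voltage - sw$ljp_offset
  seg <- split_ramp_segments(sw, protocol)
  ef <- extract_reversal(seg$forward, prev_erev = prev_erev)
  er <- extract_reversal(seg$reverse, prev_erev = prev_erev)
  avg <- average_fwd_rev(as.numeric(ef), as.numeric(er))
  v_hi <- max(protocol$v_start, protocol$v_end) - sw$ljp_offset
  v_lo <- min(protocol$v_start, protocol$v_end) - sw$ljp_offset
  g_plus <- g_minus <- j_plus <- j_minus <- NA_real_
  i_hi <- mean(seg$forward$i_pA[abs(seg$forward$v_mV - v_hi) <= 1])
  i_lo <- mean(seg$forward$i_pA[abs(seg$forward$v_mV - v_lo) <= 1])
  j_plus <- current_density(i_hi, sw$capacitance)
  j_minus <- current_density(i_lo, sw$capacitance)
  if (!is.na(avg$e_rev)) {
    if (abs(v_hi - avg$e_rev) > 1e-9) {
      g_plus <- chord_conductance(seg$forward, avg$e_rev, v_hi)
    }
    if (abs(v_lo - avg$e_rev) > 1e-9) {
      g_minus <- chord_conductance(seg$forward, avg$e_rev, v_lo)
    }
  }
  out <- data.frame(
    sweep_time = sw$sweep_time, solution_id = sw$solution_id,
    e_rev_fwd = as.numeric(ef), e_rev_rev = as.numeric(er),
    e_rev = avg$e_rev, hysteresis = avg$hysteresis,
    g_plus = g_plus, g_minus = g_minus,
    j_plus = j_plus, j_minus = j_minus,
    quality_flags = paste(avg$flags, collapse = ";"),
    stringsAsFactors = FALSE)
  class(out) <- c("ramp_features", class(out))
  out
}

#' Build an annotated feature time course from a list of sweeps
#'
#' Runs [ramp_features()] on every sweep (time-ordered; unordered input is
#' sorted with a warning) and attaches solution-switch events. Sweeps whose
#' current never reverses yield a gap (`NA`), never an interpolated value.
#'
#' @param sweeps list of [new_sweep()] objects.
#' @param protocol the acquisition [ramp_protocol()].
#' @param events optional data.frame with columns `time` (s) and `label`.
#' @return An object of class `timecourse`: data.frame of per-sweep features
#'   with attribute `events`.
#' @export
build_timecourse <- function(sweeps, protocol, events = NULL) {
  if (length(sweeps) == 0) {
    out <- data.frame()
    attr(out, "events") <- events
    class(out) <- c("timecourse", class(out))
    return(out)
  }
  st <- vapply(sweeps, function(s) s$sweep_time, numeric(1))
  if (is.unsorted(st)) {
    warning("sweeps were not time-ordered; sorting by sweep_time")
    sweeps <- sweeps[order(st)]
  }
  prev <- NULL
  rows <- vector("list", length(sweeps))
  for (k in seq_along(sweeps)) {
    rows[[k]] <- ramp_features(sweeps[[k]], protocol, prev_erev = prev)
    if (!is.na(rows[[k]]$e_rev)) prev <- rows[[k]]$e_rev
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "events") <- events
  class(out) <- c("timecourse", "data.frame")
  out
}

#' E_rev as a function of conditioning holding voltage
#'
#' Summarizes conditioning-voltage experiments: mean E_rev per holding
#' voltage plus the Spearman rank correlation between V_hold and E_rev. In
#' strongly acidic external pH the steady pH gradient under the channel
#' depends on the holding voltage (erosion stalls as V_hold approaches the
#' H+ Nernst potential), so the correlation is positive; at neutral pH it
#' vanishes.
#'
#' @param table data.frame with columns `v_hold` (mV) and `e_rev` (mV);
#'   at least 3 distinct `v_hold` levels.
#' @return list with `summary` (data.frame v_hold, mean_e_rev, n) and
#'   `spearman_rho`.
#' @export
erev_vs_vhold <- function(table) {
  stopifnot(all(c("v_hold", "e_rev") %in% names(table)))
  tab <- table[stats::complete.cases(table[, c("v_hold", "e_rev")]), ]
  if (length(unique(tab$v_hold)) < 3) {
    stop("need at least 3 distinct v_hold levels", call. = FALSE)
  }
  agg <- aggregate(e_rev ~ v_hold, data = tab, FUN = mean)
  names(agg) <- c("v_hold", "mean_e_rev")
  agg$n <- as.vector(table(factor(tab$v_hold, levels = agg$v_hold)))
  rho <- if (var(tab$e_rev) == 0) 0 else
    suppressWarnings(cor(tab$v_hold, tab$e_rev, method = "spearman"))
  list(summary = agg, spearman_rho = rho)
}
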