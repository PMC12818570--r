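#' One SSME trace
#'
#' A capacitively coupled current recording from lysosomes adsorbed on a
#' solid-supported membrane sensor, elicited by a solution jump.
#'
#' @param time time (s), strictly increasing.
#' @param current current (nA).
#' @param condition_type `"k_jump"`, `"ph_jump"` or `"ph_series"`.
#' @param condition_value K+ dose (mM), delta-pH, or pH, respectively.
#' @param blocker `"none"` or `"4AP"` (in-well background control).
#' @param sensor_id sensor label.
#' @return An object of class `ssme_trace`.
#' @export
ssme_trace <- function(time, current,
                       condition_type = c("k_jump", "ph_jump", "ph_series"),
                       condition_value, blocker = c("none", "4AP"),
                       sensor_id = "s1") {
  condition_type <- match.arg(condition_type)
  blocker <- match.arg(blocker)
  if (length(time) != length(current) || length(time) < 2) {
    stop("time and current must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing", call. = FALSE)
  structure(list(time = time, current = current,
                 condition_type = condition_type,
                 condition_value = condition_value,
                 blocker = blocker, sensor_id = sensor_id),
            class = "ssme_trace")
}

#' Subtract the 4-AP background trace
#'
#' The in-well control records the background current in the presence of
#' the channel blocker 4-AP under the same condition; the net channel
#' current is the pointwise difference after linear interpolation of the
#' background onto the signal's time base.
#'
#' @param trace signal [ssme_trace()] (blocker `"none"`).
#' @param trace_4ap background [ssme_trace()] (blocker `"4AP"`), same sensor
#'   and condition.
#' @return A net `ssme_trace` on `trace`'s time base, blocker `"none"`.
#' @export
subtract_background <- function(trace, trace_4ap) {
  stopifnot(inherits(trace, "ssme_trace"), inherits(trace_4ap, "ssme_trace"))
  if (trace$condition_type != trace_4ap$condition_type ||
      !isTRUE(all.equal(trace$condition_value, trace_4ap$condition_value)) ||
      trace$sensor_id != trace_4ap$sensor_id) {
    stop("signal and background traces have mismatched condition or sensor",
         call. = FALSE)
  }
  bg <- approx(trace_4ap$time, trace_4ap$current, xout = trace$time,
               rule = 2)$y
  out <- trace
  out$current <- trace$current - bg
  out
}

#' Peak current of a trace
#'
#' Signed extremum of largest magnitude within the response window. The
#' window start offset allows skipping an early interval where the
#' (opposite-signed) background transient dominates.
#'
#' @param trace an [ssme_trace()].
#' @param window response window `(start, end)` in s; defaults to the first
#'   second of the trace.
#' @return Peak current in nA (signed).
#' @export
peak_current <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "ssme_trace"))
  if (is.null(window)) window <- c(min(trace$time), min(trace$time) + 1)
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (!any(sel)) stop("response window contains no samples", call. = FALSE)
  i <- trace$current[sel]
  i[which.max(abs(i))]
}

#' Translocated charge (trapezoidal integral)
#'
#' @param trace an [ssme_trace()].
#' @param window integration window `(start, end)` in s; defaults to the
#'   whole trace.
#' @return Charge in nC.
#' @export
charge_integral <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "ssme_trace"))
  t <- trace$time; i <- trace$current
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    t <- t[sel]; i <- i[sel]
  }
  if (length(t) < 2) stop("integration window contains < 2 samples", call. = FALSE)
  sum(diff(t) * (i[-1] + i[-length(i)]) / 2)
}

#' Dose-interval linear slope
#'
#' Ordinary-least-squares slope of response versus dose over the points
#' falling inside a dose interval. Used with K+-jump charge series (e.g.
#' doses between 32 and 80 mM) for relative K+ permeability and with
#' pH-jump peak series (delta-pH between 0.2 and 0.8) for relative H+
#' permeability.
#'
#' @param doses,responses numeric vectors of equal length.
#' @param interval `c(lo, hi)` dose interval (inclusive).
#' @return list with `slope`, `intercept`, `n`.
#' @export
dose_slope <- function(doses, responses, interval) {
  stopifnot(length(doses) == length(responses), length(interval) == 2)
  sel <- doses >= interval[1] & doses <= interval[2]
  if (sum(sel) < 2) {
    stop("fewer than 2 data points inside the dose interval", call. = FALSE)
  }
  fit <- lm(y ~ x, data = data.frame(x = doses[sel], y = responses[sel]))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = sum(sel))
}

#' pH titration curve
#'
#' @param ph pH values, strictly monotone.
#' @param response responses (same length), typically normalized.
#' @param n_sensors number of sensors averaged into `response`.
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(ph, response, n_sensors = 1L) {
  if (length(ph) != length(response)) stop("unequal lengths", call. = FALSE)
  d <- diff(ph)
  if (!(all(d > 0) || all(d < 0))) {
    stop("`ph` must be strictly monotone", call. = FALSE)
  }
  structure(list(ph = ph, response = response,
                 n_sensors = as.integer(n_sensors)),
            class = "titration_curve")
}

#' Normalize a titration curve to a reference pH
#'
#' Divides the response by the response at `ref_ph` (exact match or nearest
#' point within 0.05 pH units). Normalization is applied per sensor before
#' averaging across sensors.
#'
#' @param curve a [titration_curve()].
#' @param ref_ph reference pH (default 7.0).
#' @return A normalized `titration_curve`.
#' @export
normalize_to_reference <- function(curve, ref_ph = 7.0) {
  stopifnot(inherits(curve, "titration_curve"))
  k <- which.min(abs(curve$ph - ref_ph))
  if (abs(curve$ph[k] - ref_ph) > 0.05) {
    stop(sprintf("no point within 0.05 pH units of the reference pH %.2f",
                 ref_ph), call. = FALSE)
  }
  ref <- curve$response[k]
  if (ref == 0) stop("reference response is zero", call. = FALSE)
  titration_curve(curve$ph, curve$response / ref, curve$n_sensors)
}

# single-site titration term, response increasing with pH
.titration_site <- function(ph, pka) 1 / (1 + 10^(pka - ph))

#' Fit single- or double-site pK_A titration models
#'
#' Least-squares fit of a sum of `n_sites` single-site titration terms with
#' independent non-negative amplitudes and Hill coefficient fixed to 1:
#' `response(pH) = sum_i w_i / (1 + 10^(pKa_i - pH))` (response increases
#' with pH; set `direction = "acid"` for the opposite orientation). The fit
#' can be restricted to a pH window (e.g. 3 to 6.5 as commonly used for
#' these titrations); by default all points are used. pK_As are returned
#' sorted ascending. A two-site fit whose midpoints fall closer than 0.3 pH
#' units is flagged as unidentifiable.
#'
#' @param curve a [titration_curve()].
#' @param n_sites 1 or 2.
#' @param fit_range optional `c(ph_lo, ph_hi)` restriction.
#' @param direction `"alkaline"` (response rises with pH, default) or
#'   `"acid"`.
#' @return list of class `titration_fit`: `pka` (sorted), `amplitude`
#'   (matching order), `r_squared`, `n`, `flag` (`NA` or
#'   `"unidentifiable"`).
#' @export
fit_titration <- function(curve, n_sites = 1, fit_range = NULL,
                          direction = c("alkaline", "acid")) {
  stopifnot(inherits(curve, "titration_curve"), n_sites %in% c(1, 2))
  direction <- match.arg(direction)
  ph <- curve$ph; y <- curve$response
  if (!is.null(fit_range)) {
    sel <- ph >= fit_range[1] & ph <= fit_range[2]
    ph <- ph[sel]; y <- y[sel]
  }
  if (length(ph) < 4 * n_sites) {
    stop("need at least 4 points in range per titration site", call. = FALSE)
  }
  dat <- data.frame(ph = ph, y = y)
  amp0 <- max(y)
  qs <- quantile(ph, c(0.25, 0.5, 0.75), names = FALSE)
  # mirrored exponent for declining-with-pH responses
  sgn <- if (direction == "acid") -1 else 1
  site <- function(ph, pka) 1 / (1 + 10^(sgn * (pka - ph)))
  fit_sites_1 <- function() {
    starts <- lapply(qs, function(p0) list(w1 = amp0, pka1 = p0))
    .multistart_lm(function(p, d) p[["w1"]] * site(d$ph, p[["pka1"]]),
                   y, dat, starts,
                   lower = c(w1 = 0, pka1 = min(ph) - 2),
                   upper = c(w1 = Inf, pka1 = max(ph) + 2))
  }
  if (n_sites == 1) {
    fit <- fit_sites_1()
    if (is.null(fit)) stop("titration fit did not converge", call. = FALSE)
    cf <- fit$par
    pkas <- unname(cf["pka1"]); amps <- unname(cf["w1"]); flag <- NA_character_
  } else {
    lo_q <- quantile(ph, c(0.2, 0.35), names = FALSE)
    hi_q <- quantile(ph, c(0.65, 0.8), names = FALSE)
    starts <- list(
      list(w1 = amp0 / 2, pka1 = lo_q[1], w2 = amp0 / 2, pka2 = hi_q[2]),
      list(w1 = amp0 / 2, pka1 = lo_q[2], w2 = amp0 / 2, pka2 = hi_q[1]),
      list(w1 = amp0 * 0.7, pka1 = qs[1], w2 = amp0 * 0.3, pka2 = qs[3]))
    model_fn <- function(p, d) {
      p[["w1"]] * site(d$ph, p[["pka1"]]) + p[["w2"]] * site(d$ph, p[["pka2"]])
    }
    fit <- .multistart_lm(model_fn, y, dat, starts,
      lower = c(w1 = 0, pka1 = min(ph) - 2, w2 = 0, pka2 = min(ph) - 2),
      upper = c(w1 = Inf, pka1 = max(ph) + 2, w2 = Inf, pka2 = max(ph) + 2))
    if (is.null(fit)) stop("titration fit did not converge", call. = FALSE)
    cf <- fit$par
    ord <- order(c(cf["pka1"], cf["pka2"]))
    pkas <- unname(c(cf["pka1"], cf["pka2"])[ord])
    amps <- unname(c(cf["w1"], cf["w2"])[ord])
    # identifiability: sites too close, a site with negligible amplitude
    # share, or no real improvement over the one-site model
    fit1 <- fit_sites_1()
    poor_gain <- !is.null(fit1) && fit$rss > 0.5 * fit1$rss
    tiny_site <- min(amps) < 0.1 * sum(amps)
    flag <- if (diff(pkas) < 0.3 || tiny_site || poor_gain) {
      "unidentifiable"
    } else NA_character_
  }
  structure(list(pka = pkas, amplitude = amps,
                 r_squared = .r_squared(y, fit$fitted),
                 n = length(ph), flag = flag),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> pK_A = %s (amplitudes %s), R^2 = %.4f%s\n",
              paste(signif(x$pka, 4), collapse = ", "),
              paste(signif(x$amplitude, 3), collapse = ", "),
              x$r_squared,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Parameters of the synthetic SSME dataset generator
#'
#' `a_k` and `a_h` scale the K+-jump charge and pH-jump peak responses; the
#' default mutant parameters encode the observed ~15-fold lower K+ and
#' ~4-fold lower H+ permeability relative to wild type.
#'
#' @param a_k K+-jump response scale (nC-equivalent).
#' @param a_h pH-jump response scale (nA-equivalent).
#' @param km_k Michaelis-type dose-saturation constant (mM) of the K+
#'   response.
#' @param dph_sat saturation scale of the pH-jump response (pH units).
#' @param gate_pka1,gate_pka2,gate_w,gate_mode,mutant_pka pH-dependence of
#'   the K+ flux (see [gate_open_fraction()]).
#' @param background_amp background transient amplitude (nA; negative for
#'   K-jump style backgrounds).
#' @param noise_sd relative noise SD applied to responses.
#' @return list of class `ssme_params`.
#' @export
ssme_params <- function(a_k = 1, a_h = 1, km_k = 40, dph_sat = 1,
                        gate_pka1 = 4.5, gate_pka2 = 7.0, gate_w = 0.5,
                        gate_mode = c("wt-double", "mutant-single"),
                        mutant_pka = 4.2,
                        background_amp = -0.5, noise_sd = 0.0) {
  gate_mode <- match.arg(gate_mode)
  structure(list(a_k = a_k, a_h = a_h, km_k = km_k, dph_sat = dph_sat,
                 gate_pka1 = gate_pka1, gate_pka2 = gate_pka2,
                 gate_w = gate_w, gate_mode = gate_mode,
                 mutant_pka = mutant_pka,
                 background_amp = background_amp, noise_sd = noise_sd),
            class = "ssme_params")
}

# titration factor for ssme_params (reuses gate_open_fraction's model shape)
.ssme_gate <- function(ph, p) {
  m <- list(gate_mode = p$gate_mode, gate_pka1 = p$gate_pka1,
            gate_pka2 = p$gate_pka2, gate_w = p$gate_w,
            mutant_pka = p$mutant_pka)
  gate_open_fraction(ph, m, "K")
}

#' Generate a synthetic SSME dataset
#'
#' Emits three condition series per sensor with a capacitive background
#' transient plus a gated signal transient and optional multiplicative
#' noise:
#' * K+-jump series at doses 2-100 mM (saturating dose dependence,
#'   quantified by charge integrals),
#' * pH-jump series at delta-pH 0.2-3 (saturating, quantified by peak
#'   currents),
#' * symmetric-pH K+-flux titration at 12 pH levels between 3.0 and 8.5
#'   (pH dependence from the params' titration model).
#'
#' For every signal trace a matching 4-AP background trace (background
#' only) is emitted, enabling [subtract_background()].
#'
#' @param params an [ssme_params()].
#' @param seed integer seed.
#' @param n_sensors number of replicate sensors.
#' @return list with `traces` (long data.frame: sensor_id, condition_type,
#'   condition_value, blocker, t_s, i_nA) and `truth` (the generating
#'   parameters).
#' @export
generate_ssme_dataset <- function(params, seed = 1L, n_sensors = 1L) {
  stopifnot(inherits(params, "ssme_params"))
  set.seed(seed)
  t_s <- seq(0, 1.5, by = 0.005)
  sig_shape <- exp(-t_s / 0.15) * (1 - exp(-t_s / 0.02))   # fast rise, slow decay
  bg_shape <- exp(-t_s / 0.05) * (1 - exp(-t_s / 0.005))   # faster transient
  doses <- c(2, 4, 8, 16, 32, 48, 64, 80, 100)
  dphs <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.5, 2.0, 2.5, 3.0)
  phs <- seq(3.0, 8.5, length.out = 12)
  rows <- list()
  emit <- function(sensor, type, value, blocker, i_nA) {
    rows[[length(rows) + 1]] <<- data.frame(
      sensor_id = sensor, condition_type = type, condition_value = value,
      blocker = blocker, t_s = t_s, i_nA = i_nA, stringsAsFactors = FALSE)
  }
  for (s in seq_len(n_sensors)) {
    sid <- sprintf("s%d", s)
    jitter <- function() 1 + params$noise_sd * rnorm(1)
    for (d in doses) {
      # fixed measurement pH: the titration factor is a constant already
      # folded into a_k, so the programmed wt/mutant slope ratio is exact
      amp <- params$a_k * d / (d + params$km_k)
      emit(sid, "k_jump", d, "4AP", params$background_amp * bg_shape)
      emit(sid, "k_jump", d, "none",
           params$background_amp * bg_shape + amp * jitter() * sig_shape)
    }
    for (dp in dphs) {
      amp <- params$a_h * (1 - exp(-dp / params$dph_sat))
      emit(sid, "ph_jump", dp, "4AP", 0.3 * bg_shape)
      emit(sid, "ph_jump", dp, "none",
           0.3 * bg_shape + amp * jitter() * sig_shape)
    }
    for (p in phs) {
      amp <- params$a_k * .ssme_gate(p, params)
      # positive signal peak read after the negative background decays
      emit(sid, "ph_series", p, "none",
           params$background_amp * bg_shape + amp * jitter() * sig_shape)
    }
  }
  list(traces = do.call(rbind, rows), truth = params)
}

#' Summarize an SSME trace table into per-condition responses
#'
#' Applies in-well background subtraction where a matching 4-AP trace
#' exists, then quantifies each signal trace: charge integral for K+-jump
#' series, peak current for pH-jump series, and windowed positive peak for
#' the symmetric-pH series (window start skips the background transient).
#'
#' @param traces long data.frame as produced by [generate_ssme_dataset()].
#' @param ph_series_window response window for the pH-series peak (s).
#' @return data.frame: sensor_id, condition_type, condition_value, response.
#' @export
summarize_ssme <- function(traces, ph_series_window = c(0.2, 1.5)) {
  key <- interaction(traces$sensor_id, traces$condition_type,
                     traces$condition_value, drop = TRUE)
  out <- lapply(split(traces, key), function(d) {
    sig <- d[d$blocker == "none", ]
    bg <- d[d$blocker == "4AP", ]
    tr <- ssme_trace(sig$t_s, sig$i_nA, sig$condition_type[1],
                     sig$condition_value[1], "none", sig$sensor_id[1])
    if (nrow(bg) > 0) {
      trb <- ssme_trace(bg$t_s, bg$i_nA, bg$condition_type[1],
                        bg$condition_value[1], "4AP", bg$sensor_id[1])
      tr <- subtract_background(tr, trb)
    }
    resp <- switch(tr$condition_type,
      k_jump = charge_integral(tr),
      ph_jump = peak_current(tr),
      ph_series = peak_current(tr, window = ph_series_window))
    data.frame(sensor_id = tr$sensor_id, condition_type = tr$condition_type,
               condition_value = tr$condition_value, response = resp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sensor_id, out$condition_type, out$condition_value), ]
}
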