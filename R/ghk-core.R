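#' Ionic conditions on both membrane faces
#'
#' Bundles the K+ and Cs+ concentrations, pH values and temperature that
#' enter the GHK permeability-ratio equations. "ex" is the
#' extracellular/luminal face, "in" the cytosolic face. Because Cs+ permeates
#' these channels about as well as K+ (P_Cs/P_K close to 1), analyses
#' normally use effective K+ concentrations obtained with [effective_k()];
#' this constructor does not apply the correction itself.
#'
#' @param k_ex,k_in K+ concentration (mM) on the external/internal face.
#' @param ph_ex,ph_in pH on the external/internal face.
#' @param cs_ex,cs_in Cs+ concentration (mM); kept for bookkeeping so that a
#'   pipeline can apply or skip the Cs correction explicitly.
#' @param temperature absolute temperature in K.
#' @return An object of class `ionic_conditions`.
#' @examples
#' cond <- ionic_conditions(k_ex = 145, k_in = 145, ph_ex = 4.7, ph_in = 7.4)
#' @export
ionic_conditions <- function(k_ex, k_in, ph_ex, ph_in,
                             cs_ex = 0, cs_in = 0,
                             temperature = DEFAULT_TEMPERATURE) {
  conc <- c(k_ex = k_ex, k_in = k_in, cs_ex = cs_ex, cs_in = cs_in)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  .check_ph(ph_ex, "ph_ex"); .check_ph(ph_in, "ph_in")
  .check_temperature(temperature)
  structure(
    list(k_ex = k_ex, k_in = k_in, cs_ex = cs_ex, cs_in = cs_in,
         ph_ex = ph_ex, ph_in = ph_in, temperature = temperature),
    class = "ionic_conditions"
  )
}

#' @export
print.ionic_conditions <- function(x, ...) {
  cat(sprintf(
    "<ionic_conditions> K+ %g/%g mM, Cs+ %g/%g mM (ex/in), pH %g/%g, T = %g K\n",
    x$k_ex, x$k_in, x$cs_ex, x$cs_in, x$ph_ex, x$ph_in, x$temperature))
  invisible(x)
}

#' K+ concentration jump
#'
#' Describes an external K+ concentration change used to measure a
#' reversal-potential shift (delta E_rev) at fixed external pH, the input of
#' [ratio_from_delta_erev()].
#'
#' @param k_ex_1,k_ex_2 external K+ (mM) before and after the jump; must
#'   differ and both be positive.
#' @param ph_ex external pH (unchanged by the jump).
#' @param temperature absolute temperature in K.
#' @return An object of class `k_jump`.
#' @export
k_jump <- function(k_ex_1, k_ex_2, ph_ex, temperature = DEFAULT_TEMPERATURE) {
  if (!is.finite(k_ex_1) || !is.finite(k_ex_2) || k_ex_1 <= 0 || k_ex_2 <= 0) {
    stop("both K+ concentrations must be positive", call. = FALSE)
  }
  if (k_ex_1 == k_ex_2) stop("k_ex_1 and k_ex_2 must differ", call. = FALSE)
  .check_ph(ph_ex, "ph_ex"); .check_temperature(temperature)
  structure(list(k_ex_1 = k_ex_1, k_ex_2 = k_ex_2, ph_ex = ph_ex,
                 temperature = temperature),
            class = "k_jump")
}

#' Nernst equilibrium potential
#'
#' @param c_out,c_in concentrations of the ion outside/inside (any common
#'   unit, both positive).
#' @param valence ionic valence z (non-zero integer).
#' @param temperature absolute temperature in K.
#' @return Equilibrium potential in mV (inside relative to outside of zero).
#' @examples
#' nernst_potential(14, 140, temperature = 298.15) # about -59.2 mV
#' @export
nernst_potential <- function(c_out, c_in, valence = 1L,
                             temperature = DEFAULT_TEMPERATURE) {
  if (any(!is.finite(c(c_out, c_in))) || any(c_out <= 0) || any(c_in <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (valence == 0) stop("`valence` must be non-zero", call. = FALSE)
  .check_temperature(temperature)
  1000 * .rt_over_f(temperature) / valence * log(c_out / c_in)
}

#' Effective K+ concentration with the Cs+ correction
#'
#' Recording solutions typically contain a few mM Cs+ to block endogenous K+
#' channels. Since the channel's Cs+ permeability is close to its K+
#' permeability, the Cs+ concentration is added to the nominal K+
#' concentration before evaluating the GHK ratio equations.
#'
#' @param nominal_k nominal K+ (mM), >= 0.
#' @param cs Cs+ (mM), >= 0.
#' @return Effective K+ concentration in mM.
#' @examples
#' effective_k(140, 5) # 145
#' @export
effective_k <- function(nominal_k, cs) {
  if (any(!is.finite(c(nominal_k, cs))) || any(nominal_k < 0) || any(cs < 0)) {
    stop("`nominal_k` and `cs` must be >= 0", call. = FALSE)
  }
  nominal_k + cs
}

#' Permeability-ratio result container
#'
#' @param value geometric-mean P_H/P_K ratio (> 0).
#' @param gsd geometric SD factor (>= 1); spread is reported as value
#'   multiplied-or-divided by gsd.
#' @param n number of underlying measurements.
#' @return An object of class `permeability_ratio`.
#' @export
permeability_ratio <- function(value, gsd = 1, n = 1L) {
  if (!is.finite(value) || value <= 0) {
    stop("permeability ratio must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(gsd) || gsd < 1) stop("`gsd` must be >= 1", call. = FALSE)
  structure(list(value = value, gsd = gsd, n = as.integer(n)),
            class = "permeability_ratio")
}

#' @export
print.permeability_ratio <- function(x, ...) {
  cat(sprintf("<permeability_ratio> P_H+/P_K+ = %.4g x/÷ %.3g (n = %d)\n",
              x$value, x$gsd, x$n))
  invisible(x)
}

# exp(F E / RT) with E in mV
.volt_factor <- function(e_mv, temperature) {
  exp((e_mv / 1000) / .rt_over_f(temperature))
}

#' P_H+/P_K+ from an absolute reversal potential
#'
#' Evaluates the GHK permeability-ratio equation for a two-ion (H+, K+)
#' channel from a measured reversal potential:
#' \deqn{P_H/P_K = \frac{[K]_{ex} - [K]_{in} e^{FE/RT}}
#'                      {10^{-pH_{in}} e^{FE/RT} - 10^{-pH_{ex}}}}
#' with K+ converted to mol/L so that it is commensurate with the proton
#' concentration 10^(-pH) mol/L. The caller is responsible for supplying
#' Cs-corrected K+ concentrations (see [effective_k()]).
#'
#' A physically consistent E_rev lies strictly between the K+ and H+ Nernst
#' potentials and yields a positive ratio. E_rev at the H+ Nernst potential
#' makes the denominator vanish (singularity); an E_rev outside the
#' bracketing interval yields a negative ratio and is rejected, because
#' downstream geometric aggregation requires positivity.
#'
#' @param cond an [ionic_conditions()] object.
#' @param e_rev measured reversal potential in mV.
#' @return A [permeability_ratio()] with `n = 1`.
#' @examples
#' cond <- ionic_conditions(145, 145, ph_ex = 4.7, ph_in = 7.4,
#'                          temperature = 295)
#' ratio_from_erev(cond, 52.5)$value # about 5.1e4
#' @export
ratio_from_erev <- function(cond, e_rev) {
  stopifnot(inherits(cond, "ionic_conditions"))
  ef <- .volt_factor(e_rev, cond$temperature)
  num <- .mm_to_molar(cond$k_ex) - .mm_to_molar(cond$k_in) * ef
  den <- .ph_to_molar(cond$ph_in) * ef - .ph_to_molar(cond$ph_ex)
  if (abs(den) < 1e-12 * (.ph_to_molar(cond$ph_in) * ef +
                          .ph_to_molar(cond$ph_ex))) {
    stop("E_rev at the H+ Nernst potential: ratio is singular", call. = FALSE)
  }
  # numerically vanishing numerator (E_rev at E_K+): the ratio is zero
  if (abs(num) < 1e-12 * (.mm_to_molar(cond$k_ex) + .mm_to_molar(cond$k_in))) {
    num <- 0
  }
  val <- num / den
  if (val < 0) {
    stop(sprintf(
      "inconsistent input: E_rev = %g mV lies outside the [E_K+, E_H+] bracket (ratio would be negative)",
      e_rev), call. = FALSE)
  }
  if (val == 0) {
    return(structure(list(value = 0, gsd = 1, n = 1L),
                     class = "permeability_ratio"))
  }
  permeability_ratio(val, gsd = 1, n = 1L)
}

#' P_H+/P_K+ from the reversal-potential shift after a K+ jump
#'
#' Evaluates the jump form of the GHK permeability-ratio equation,
#' \deqn{P_H/P_K = \frac{[K]_{ex,2} - [K]_{ex,1} e^{F\Delta E/RT}}
#'                      {10^{-pH_{ex}} (e^{F\Delta E/RT} - 1)}}
#' which only requires the change in reversal potential caused by switching
#' the external K+ concentration at fixed external pH. Valid only if the
#' transmembrane pH gradient (and hence E_rev) was stable before the jump;
#' that is the caller's responsibility.
#'
#' @param jump a [k_jump()] object.
#' @param delta_erev E_rev(after) - E_rev(before) in mV; must be non-zero.
#' @return A [permeability_ratio()] with `n = 1`.
#' @examples
#' j <- k_jump(145, 19, ph_ex = 4.7, temperature = 295)
#' ratio_from_delta_erev(j, -3.8)$value # about 3.8e4
#' @export
ratio_from_delta_erev <- function(jump, delta_erev) {
  stopifnot(inherits(jump, "k_jump"))
  if (delta_erev == 0) {
    stop("delta_erev = 0: denominator vanishes (singular)", call. = FALSE)
  }
  ef <- .volt_factor(delta_erev, jump$temperature)
  num <- .mm_to_molar(jump$k_ex_2) - .mm_to_molar(jump$k_ex_1) * ef
  den <- .ph_to_molar(jump$ph_ex) * (ef - 1)
  # numerically vanishing numerator (Nernstian shift): the ratio is zero
  if (abs(num) < 1e-12 * (.mm_to_molar(jump$k_ex_1) + .mm_to_molar(jump$k_ex_2))) {
    num <- 0
  }
  val <- num / den
  if (val < 0) {
    stop("inconsistent input: delta_erev implies a negative ratio", call. = FALSE)
  }
  if (val == 0) {
    return(structure(list(value = 0, gsd = 1, n = 1L),
                     class = "permeability_ratio"))
  }
  permeability_ratio(val, gsd = 1, n = 1L)
}

#' Zero-current (reversal) potential implied by a permeability ratio
#'
#' Closed-form inversion of the two-ion GHK ratio equation: the GHK voltage
#' equation for H+ and K+ with P_H/P_K = `ratio`,
#' \deqn{E = \frac{RT}{F}\ln\frac{[K]_{ex} + r\,10^{-pH_{ex}}}
#'                              {[K]_{in} + r\,10^{-pH_{in}}}}
#' (concentrations in mol/L). Round-trips with [ratio_from_erev()] to
#' relative error below 1e-9; also the simulator's instantaneous zero-current
#' potential.
#'
#' @param cond an [ionic_conditions()] object.
#' @param ratio P_H/P_K, >= 0 (0 gives the K+-only Nernst potential).
#' @return Reversal potential in mV.
#' @export
erev_from_ratio <- function(cond, ratio) {
  stopifnot(inherits(cond, "ionic_conditions"))
  if (!is.finite(ratio) || ratio < 0) stop("`ratio` must be >= 0", call. = FALSE)
  num <- .mm_to_molar(cond$k_ex) + ratio * .ph_to_molar(cond$ph_ex)
  den <- .mm_to_molar(cond$k_in) + ratio * .ph_to_molar(cond$ph_in)
  if (num <= 0 || den <= 0) {
    stop("all permeant concentrations are zero on one side", call. = FALSE)
  }
  1000 * .rt_over_f(cond$temperature) * log(num / den)
}

#' GHK current for a single ion
#'
#' Standard Goldman-Hodgkin-Katz flux equation. With the lumped permeability
#' `permeability` expressed as permeability x membrane area (L/s) and
#' concentrations in mol/L, the returned current is in amperes; outward
#' cation current is positive. At v = 0 the analytic limit
#' P F z (c_in - c_out) is used.
#'
#' The zero-current voltage of the summed H+ + K+ currents with
#' P_H/P_K = r equals [erev_from_ratio()] for the same conditions.
#'
#' @param permeability lumped permeability (permeability times area, L/s).
#' @param valence ionic valence z.
#' @param c_in,c_out internal/external concentration in mol/L (>= 0).
#' @param v membrane potential in mV.
#' @param temperature absolute temperature in K.
#' @return Current in A (vectorized over `v`).
#' @export
ghk_current <- function(permeability, valence = 1L, c_in, c_out, v,
                        temperature = DEFAULT_TEMPERATURE) {
  if (any(c(c_in, c_out) < 0)) stop("concentrations must be >= 0", call. = FALSE)
  u <- valence * (v / 1000) / .rt_over_f(temperature)  # dimensionless
  # I = P z F u (c_in - c_out e^-u) / (1 - e^-u); u -> 0 limit: P z F (c_in - c_out)
  small <- abs(u) < 1e-8
  out <- numeric(length(u))
  if (any(small)) {
    out[small] <- permeability * valence * .FARADAY * (c_in - c_out)
  }
  if (any(!small)) {
    uu <- u[!small]
    em <- exp(-uu)
    out[!small] <- permeability * valence * .FARADAY * uu *
      (c_in - c_out * em) / (1 - em)
  }
  out
}

#' Lumped permeability giving a target chord conductance
#'
#' Converts a conductance (nS) measured under symmetric concentration
#' `c_ref` (mol/L) into the lumped GHK permeability (L/s) used by
#' [ghk_current()] and the simulator: under symmetric concentrations the GHK
#' current is ohmic with g = P z^2 F^2 c / (RT).
#'
#' @param g_ns chord conductance in nS.
#' @param c_ref symmetric reference concentration in mol/L.
#' @param valence ionic valence.
#' @param temperature absolute temperature in K.
#' @return Lumped permeability in L/s.
#' @export
permeability_from_conductance <- function(g_ns, c_ref, valence = 1L,
                                          temperature = DEFAULT_TEMPERATURE) {
  if (c_ref <= 0) stop("`c_ref` must be positive", call. = FALSE)
  g <- g_ns * 1e-9
  g * .GAS_CONSTANT * temperature / (valence^2 * .FARADAY^2 * c_ref)
}

#' Geometric aggregation of permeability ratios
#'
#' Permeability ratios are lognormally distributed across cells, so summaries
#' are reported as geometric mean with a geometric SD factor ("x/÷"
#' spread): value = exp(mean(log v)), gsd = exp(sd(log v)) with the sample
#' (n-1) SD.
#'
#' @param values numeric vector of positive ratios (or a list of
#'   [permeability_ratio()] objects).
#' @return A [permeability_ratio()] with `n = length(values)`.
#' @examples
#' aggregate_geometric(c(10, 1000))$value # 100
#' @export
aggregate_geometric <- function(values) {
  if (is.list(values)) {
    values <- vapply(values, function(x) {
      if (inherits(x, "permeability_ratio")) x$value else as.numeric(x)
    }, numeric(1))
  }
  if (length(values) == 0) stop("no values to aggregate", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  lv <- log(values)
  gsd <- if (length(lv) > 1) exp(sd(lv)) else 1
  permeability_ratio(exp(mean(lv)), gsd = gsd, n = length(values))
}
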