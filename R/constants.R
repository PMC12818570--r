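# Physical constants (CODATA 2018)
.FARADAY <- 96485.33212      # C/mol
.GAS_CONSTANT <- 8.31446262  # J/(mol K)

#' Default recording temperature
#'
#' 295.15 K (22 C), the midpoint of the usual room-temperature range for
#' patch-clamp recordings (20 to 25 C). All selectivity operations take an
#' explicit temperature; this is only the default.
#' @export
DEFAULT_TEMPERATURE <- 295.15

# RT/F in volts
.rt_over_f <- function(temperature) .GAS_CONSTANT * temperature / .FARADAY

.check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature < 273 || temperature > 320) {
    stop("`temperature` must be a single value in [273, 320] K", call. = FALSE)
  }
  invisible(temperature)
}

.check_ph <- function(ph, name = "pH") {
  if (!is.numeric(ph) || any(!is.finite(ph)) || any(ph <= 0) || any(ph >= 14)) {
    stop(sprintf("`%s` must lie strictly between 0 and 14", name), call. = FALSE)
  }
  invisible(ph)
}

# mM -> mol/L
.mm_to_molar <- function(x) x / 1000

# proton concentration (mol/L) from pH
.ph_to_molar <- function(ph) 10^(-ph)
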