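# Deterministic multi-start Levenberg-Marquardt least squares.
# model_fn(par, data) returns predictions for the named parameter vector;
# each start is a named list. Returns NULL if no start converges, else
# list(par, fitted, rss).
.multistart_lm <- function(model_fn, y, data, starts, lower = NULL,
                           upper = NULL) {
  best <- NULL
  for (st in starts) {
    par0 <- unlist(st)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0,
        lower = if (is.null(lower)) NULL else lower[names(par0)],
        upper = if (is.null(upper)) NULL else upper[names(par0)],
        fn = function(p) y - model_fn(p, data),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) {
      par <- stats::setNames(as.numeric(fit$par), names(par0))
      best <- list(par = par, fitted = model_fn(par, data), rss = rss)
    }
  }
  best
}

.r_squared <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - fitted)^2) / ss_tot
}

#' Single-exponential fit of the E_rev backshift
#'
#' After external acidification the reversal potential peaks and then
#' decays ("backshift") toward baseline as the channel's own proton flux
#' erodes the pH gradient. This fits
#' `E(t) = offset + amplitude * exp(-(t - peak_time)/tau)` by least squares
#' to the records from `peak_time` to the last record before the next
#' solution event (or the end of the time course).
#'
#' The offset is a free parameter: E_rev returns toward, but not exactly to,
#' 0 mV. Initialization uses three deterministic starts from data quantiles;
#' no randomness is involved.
#'
#' @param timecourse a [build_timecourse()] result or any data.frame with
#'   columns `sweep_time` (s) and `e_rev` (mV).
#' @param peak_time experiment-clock time (s) of the E_rev peak. Defaults to
#'   the argmax of `e_rev` after `after_event` (or globally).
#' @param after_event optional event label; the peak is searched after that
#'   event's time.
#' @return list of class `decay_fit`: `amplitude` (mV), `tau` (s), `offset`
#'   (mV), `r_squared`, `fit_window`, `n`.
#' @export
fit_erev_decay <- function(timecourse, peak_time = NULL, after_event = NULL) {
  tc <- as.data.frame(timecourse)
  tc <- tc[!is.na(tc$e_rev), c("sweep_time", "e_rev")]
  events <- attr(timecourse, "events")
  if (is.null(peak_time)) {
    from <- -Inf
    if (!is.null(after_event) && !is.null(events)) {
      hit <- events$time[events$label == after_event]
      if (length(hit)) from <- hit[1]
    }
    cand <- tc[tc$sweep_time >= from, ]
    if (nrow(cand) == 0) stop("no records after the event", call. = FALSE)
    peak_time <- cand$sweep_time[which.max(cand$e_rev)]
  }
  t_end <- Inf
  if (!is.null(events)) {
    later <- events$time[events$time > peak_time]
    if (length(later)) t_end <- min(later)
  }
  dat <- tc[tc$sweep_time >= peak_time & tc$sweep_time < t_end, ]
  if (nrow(dat) < 5) stop("need at least 5 records after the peak", call. = FALSE)
  y <- dat$e_rev
  if (y[length(y)] >= y[1]) {
    stop("E_rev is not decreasing after the stated peak; no decay to fit",
         call. = FALSE)
  }
  dat$tt <- dat$sweep_time - peak_time
  span <- diff(range(dat$tt))
  amp0 <- y[1] - min(y)
  # data-derived start: time at which the excursion has fallen to 1/e
  k_e <- which(y <= min(y) + amp0 * exp(-1))[1]
  tau_e <- if (!is.na(k_e) && dat$tt[k_e] > 0) dat$tt[k_e] else 0.3 * span
  starts <- lapply(unique(c(tau_e, c(0.03, 0.1, 0.3, 1) * span)),
                   function(tau0) {
    list(amplitude = amp0, tau = tau0, offset = min(y))
  })
  model_fn <- function(p, d) p[["offset"]] + p[["amplitude"]] * exp(-d$tt / p[["tau"]])
  # bounds keep the fit in the physically meaningful regime (a decaying
  # excursion toward a baseline near the data), excluding the degenerate
  # large-amplitude/large-offset cancellation along the linear direction
  rng <- diff(range(y))
  fit <- .multistart_lm(model_fn, y, dat, starts,
                        lower = c(amplitude = 0, tau = 1e-6,
                                  offset = min(y) - 2 * rng),
                        upper = c(amplitude = 10 * rng, tau = 100 * span,
                                  offset = max(y)))
  if (is.null(fit)) {
    stop("exponential fit did not converge (n = ", nrow(dat),
         ", range = ", signif(diff(range(y)), 3), " mV)", call. = FALSE)
  }
  cf <- fit$par
  structure(list(amplitude = unname(cf["amplitude"]),
                 tau = unname(cf["tau"]),
                 offset = unname(cf["offset"]),
                 r_squared = .r_squared(y, fit$fitted),
                 fit_window = c(peak_time, max(dat$sweep_time)),
                 n = nrow(dat)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> tau = %.3g s, amplitude = %.3g mV, offset = %.3g mV, R^2 = %.4f (n = %d)\n",
              x$tau, x$amplitude, x$offset, x$r_squared, x$n))
  invisible(x)
}

#' Linear regression of 1/tau on conductance
#'
#' The erosion model predicts that the backshift rate 1/tau is proportional
#' to the proton chord conductance; this performs the corresponding
#' ordinary-least-squares regression of 1/tau on G (conventionally G at
#' -120 mV, 90 s after acidification).
#'
#' @param pairs data.frame with columns `g` (nS) and `tau` (s), all tau > 0;
#'   at least 3 pairs.
#' @return list of class `linear_fit`: `slope`, `intercept`, `r_squared`,
#'   `pearson_r`, `n`.
#' @export
fit_invtau_vs_g <- function(pairs) {
  stopifnot(all(c("g", "tau") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[, c("g", "tau")]), ]
  if (nrow(pairs) < 3) stop("need at least 3 (g, tau) pairs", call. = FALSE)
  if (any(pairs$tau <= 0)) stop("all tau must be positive", call. = FALSE)
  if (var(pairs$g) == 0) stop("degenerate fit: no variance in g", call. = FALSE)
  y <- 1 / pairs$tau
  fit <- lm(y ~ g, data = data.frame(g = pairs$g, y = y))
  r <- cor(pairs$g, y)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r^2,  # simple regression: R^2 = r^2
                 pearson_r = r, n = nrow(pairs)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope = %.4g, intercept = %.4g, R^2 = %.4f, r = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$pearson_r, x$n))
  invisible(x)
}

#' Hill fit of peak E_rev versus backshift time constant
#'
#' Cells with slow erosion (large tau) reach reversal-potential peaks close
#' to the undisturbed GHK value; fast erosion truncates the peak. The
#' saturating relation is modeled with the Hill equation
#' `peak(tau) = e_max * tau^h / (tau_half^h + tau^h)`; `e_max` estimates the
#' undisturbed peak E_rev. The Hill coefficient is fitted freely and
#' reported. Points with tau above `tau_flag` (default 40 s) are flagged:
#' their peaks are closest to the undisturbed value and are the ones
#' selectivity pipelines should feed into the GHK ratio equation.
#'
#' @param pairs data.frame with columns `tau` (s) and `peak_e_rev` (mV);
#'   at least 4 pairs with distinct tau.
#' @param tau_flag threshold (s) above which points are flagged as
#'   quasi-undisturbed.
#' @return list of class `hill_fit`: `e_max` (mV), `tau_half` (s),
#'   `hill_coef`, `r_squared`, `n`, `flagged` (logical vector).
#' @export
fit_peak_vs_tau <- function(pairs, tau_flag = 40) {
  stopifnot(all(c("tau", "peak_e_rev") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[, c("tau", "peak_e_rev")]), ]
  if (nrow(pairs) < 4) stop("need at least 4 (tau, peak) pairs", call. = FALSE)
  if (length(unique(pairs$tau)) < 2) {
    stop("unidentifiable fit: all pairs share one tau", call. = FALSE)
  }
  emax0 <- max(pairs$peak_e_rev)
  qs <- quantile(pairs$tau, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- unlist(lapply(qs, function(th) {
    lapply(c(1, 2), function(h0) list(e_max = emax0, tau_half = th,
                                      hill_coef = h0))
  }), recursive = FALSE)
  model_fn <- function(p, d) {
    p[["e_max"]] * d$tau^p[["hill_coef"]] /
      (p[["tau_half"]]^p[["hill_coef"]] + d$tau^p[["hill_coef"]])
  }
  fit <- .multistart_lm(model_fn, pairs$peak_e_rev, pairs, starts,
                        lower = c(e_max = -Inf, tau_half = 1e-6, hill_coef = 0.1),
                        upper = c(e_max = Inf, tau_half = Inf, hill_coef = 20))
  if (is.null(fit)) stop("Hill fit did not converge", call. = FALSE)
  cf <- fit$par
  structure(list(e_max = unname(cf["e_max"]),
                 tau_half = unname(cf["tau_half"]),
                 hill_coef = unname(cf["hill_coef"]),
                 r_squared = .r_squared(pairs$peak_e_rev, fit$fitted),
                 n = nrow(pairs),
                 flagged = pairs$tau > tau_flag),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> e_max = %.3g mV, tau_half = %.3g s, h = %.3g, R^2 = %.4f (n = %d, %d flagged)\n",
              x$e_max, x$tau_half, x$hill_coef, x$r_squared, x$n, sum(x$flagged)))
  invisible(x)
}
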