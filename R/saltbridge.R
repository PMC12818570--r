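#' Per-frame minimum-distance series for a residue pair
#'
#' @param time frame times (ns), increasing.
#' @param distance minimum donor-acceptor distances (Angstrom), > 0.
#' @param pair_label e.g. `"H57-A:D279-A"`.
#' @param state_label channel-state group, e.g. `"open-protonated"`.
#' @param replica_id replica label.
#' @return An object of class `distance_series`.
#' @export
distance_series <- function(time, distance, pair_label = "pair",
                            state_label = "state", replica_id = "r1") {
  if (length(time) != length(distance)) stop("unequal lengths", call. = FALSE)
  if (any(diff(time) <= 0)) stop("`time` must be increasing", call. = FALSE)
  if (any(distance <= 0)) stop("distances must be positive", call. = FALSE)
  structure(list(time = time, distance = distance, pair_label = pair_label,
                 state_label = state_label, replica_id = replica_id),
            class = "distance_series")
}

#' @export
as.data.frame.distance_series <- function(x, ...) {
  data.frame(frame_time_ns = x$time, distance_A = x$distance,
             pair_label = x$pair_label, state = x$state_label,
             replica = x$replica_id, stringsAsFactors = FALSE)
}

#' Per-frame minimum distance between two atom groups
#'
#' For each frame, the minimum over all donor-acceptor atom pairs of the
#' Euclidean distance (e.g. both imidazole nitrogens of a histidine against
#' all carboxylate oxygens of an aspartate/glutamate). Coordinates are
#' assumed unwrapped; periodic-boundary minimum-image handling is the
#' exporter's responsibility.
#'
#' @param donor_coords,acceptor_coords arrays of dimension
#'   `frames x atoms x 3` (Angstrom); a `frames x 3` matrix is accepted for
#'   a single atom.
#' @param time optional frame times (ns); defaults to 0-based frame index.
#' @param ... passed to [distance_series()] (labels).
#' @return A [distance_series()].
#' @export
min_pair_distance <- function(donor_coords, acceptor_coords, time = NULL,
                              ...) {
  fix <- function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(nrow(a), 1, ncol(a)))
    if (length(dim(a)) != 3 || dim(a)[3] != 3) {
      stop("coordinates must be frames x atoms x 3", call. = FALSE)
    }
    a
  }
  d <- fix(donor_coords); a <- fix(acceptor_coords)
  if (dim(d)[1] != dim(a)[1]) stop("frame counts differ", call. = FALSE)
  if (dim(d)[2] < 1 || dim(a)[2] < 1) stop("empty atom group", call. = FALSE)
  nf <- dim(d)[1]
  dist <- vapply(seq_len(nf), function(f) {
    dm <- Inf
    for (i in seq_len(dim(d)[2])) {
      for (j in seq_len(dim(a)[2])) {
        dd <- sqrt(sum((d[f, i, ] - a[f, j, ])^2))
        if (dd < dm) dm <- dd
      }
    }
    dm
  }, numeric(1))
  if (is.null(time)) time <- seq_len(nf) - 1
  distance_series(time, dist, ...)
}

#' Discard the equilibration burn-in of a distance series
#'
#' @param series a [distance_series()].
#' @param burn_in frames with `time < burn_in` (ns) are removed
#'   (default 50 ns).
#' @return The trimmed series; attribute `n_removed` records the cut.
#'   A series entirely inside the burn-in returns an empty series with a
#'   warning.
#' @export
apply_burn_in <- function(series, burn_in = 50) {
  stopifnot(inherits(series, "distance_series"), burn_in >= 0)
  keep <- series$time >= burn_in
  if (!any(keep)) warning("series lies entirely within the burn-in window")
  out <- series
  out$time <- series$time[keep]
  out$distance <- series$distance[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Contact fractions and area-normalized histogram of pooled distances
#'
#' Pools the frames of one or more distance series (replica concatenation;
#' order-invariant) and reports, for each threshold, the fraction of frames
#' with distance strictly below it, together with a density histogram whose
#' total area is 1.
#'
#' @param series a [distance_series()] or list of them (pooled).
#' @param thresholds distance thresholds in Angstrom (default the
#'   conventional salt-bridge cutoffs 3.2 and 4.0).
#' @param bin_width histogram bin width (Angstrom).
#' @param range histogram range (Angstrom); widened if data fall outside.
#' @return list of class `contact_summary`: `fraction_below` (named),
#'   `histogram` (data.frame mid, density), `bin_edges`, `n_frames_used`.
#' @export
contact_fraction <- function(series, thresholds = c(3.2, 4.0),
                             bin_width = 0.1, range = c(1.5, 12)) {
  if (inherits(series, "distance_series")) series <- list(series)
  d <- unlist(lapply(series, function(s) s$distance))
  if (length(d) == 0) stop("no frames after burn-in", call. = FALSE)
  thresholds <- sort(thresholds)
  frac <- vapply(thresholds, function(th) mean(d < th), numeric(1))
  names(frac) <- format(thresholds)
  lo <- min(range[1], floor(min(d) / bin_width) * bin_width)
  hi <- max(range[2], ceiling(max(d) / bin_width) * bin_width)
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  density <- counts / (sum(counts) * bin_width)
  structure(list(fraction_below = frac,
                 histogram = data.frame(mid = edges[-length(edges)] +
                                          bin_width / 2,
                                        density = density),
                 bin_edges = edges,
                 n_frames_used = length(d)),
            class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf("<contact_summary> %d frames; fraction below: %s\n",
              x$n_frames_used,
              paste(sprintf("%s A -> %.3f", names(x$fraction_below),
                            x$fraction_below), collapse = ", ")))
  invisible(x)
}

#' Contact-fraction heatmap matrix by channel state and residue pair
#'
#' Groups distance series by `(state_label, pair_label)`, pools replicas
#' within each group and computes the contact fraction at `threshold`.
#' Rows are channel-state groups, columns residue-pair combinations; a pair
#' missing from a state yields `NA`.
#'
#' @param series_list list of [distance_series()].
#' @param threshold contact threshold in Angstrom (default 3.2).
#' @return numeric matrix (states x pairs) of contact fractions.
#' @export
contact_heatmap <- function(series_list, threshold = 3.2) {
  stopifnot(length(series_list) > 0)
  states <- unique(vapply(series_list, `[[`, "", "state_label"))
  pairs <- unique(vapply(series_list, `[[`, "", "pair_label"))
  m <- matrix(NA_real_, length(states), length(pairs),
              dimnames = list(states, pairs))
  for (st in states) {
    for (pr in pairs) {
      grp <- Filter(function(s) s$state_label == st && s$pair_label == pr,
                    series_list)
      if (length(grp) > 0) {
        m[st, pr] <- contact_fraction(grp, thresholds = threshold)$
          fraction_below[[1]]
      }
    }
  }
  m
}

#' Generate a two-state synthetic salt-bridge distance series
#'
#' Telegraph (two-state Markov) surrogate for salt-bridge dynamics: the
#' contact alternates between a bound state (default 2.9 +/- 0.2 Angstrom)
#' and an unbound state (default 7 +/- 1.5 Angstrom) with exponential
#' dwell times, plus Gaussian jitter truncated at 1.5 Angstrom.
#'
#' @param bound_mean,bound_sd,unbound_mean,unbound_sd state distance
#'   distributions (Angstrom).
#' @param rate_unbind,rate_bind switching rates (1/ns).
#' @param duration_ns,dt_ns series length and frame spacing (ns).
#' @param start_bound start in the bound state?
#' @param seed integer seed.
#' @param ... labels passed to [distance_series()].
#' @return A [distance_series()]; attribute `bound` is the underlying
#'   state indicator.
#' @export
generate_distance_series <- function(bound_mean = 2.9, bound_sd = 0.2,
                                     unbound_mean = 7, unbound_sd = 1.5,
                                     rate_unbind = 0.02, rate_bind = 0.02,
                                     duration_ns = 1000, dt_ns = 1,
                                     start_bound = TRUE, seed = 1L, ...) {
  stopifnot(bound_mean > 0, unbound_mean > 0)
  set.seed(seed)
  time <- seq(0, duration_ns, by = dt_ns)
  n <- length(time)
  bound <- logical(n)
  bound[1] <- start_bound
  p_ub <- 1 - exp(-rate_unbind * dt_ns)  # bound -> unbound per frame
  p_b <- 1 - exp(-rate_bind * dt_ns)
  u <- runif(n)
  for (k in 2:n) {
    bound[k] <- if (bound[k - 1]) u[k] > p_ub else u[k] <= p_b
  }
  mu <- ifelse(bound, bound_mean, unbound_mean)
  sdv <- ifelse(bound, bound_sd, unbound_sd)
  d <- pmax(1.5, rnorm(n, mu, sdv))
  out <- distance_series(time, d, ...)
  attr(out, "bound") <- bound
  out
}
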