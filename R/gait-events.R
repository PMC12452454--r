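#' Detect the single-limb-support window from contralateral GRF
#'
#' Single-limb support (SLS) of the analyzed limb is the period when the
#' contralateral foot is off the ground: the first maximal run of consecutive
#' contralateral vertical-GRF samples strictly below the threshold (10 N by
#' convention), ending on the last sample before the force rises to or above
#' the threshold again. A run touching either end of the series cannot be
#' certified as a complete support window and raises a "truncated SLS" error.
#' All below-threshold runs are attached for diagnostics.
#'
#' @param contra_grf `uniform_series` of contralateral vertical GRF in N
#'   (low-pass filtered at 10 Hz in the default pipeline).
#' @param threshold Threshold in N (default 10).
#' @return Object of class `sls_interval`: `start_index`/`end_index`
#'   (1-based, inclusive), `start_time`/`end_time` (s), `rate`, `threshold`,
#'   and a `runs` data frame of all below-threshold runs.
#' @examples
#' g <- uniform_series(c(600, 400, 9.9, 0, 0, 5, 9, 300), rate = 100, units = "N")
#' detect_sls(g)  # samples 3..7 (1-based)
#' @export
detect_sls <- function(contra_grf, threshold = 10) {
  stopifnot(inherits(contra_grf, "uniform_series"))
  below <- contra_grf$values < threshold
  if (!any(below)) {
    stop("detect_sls: no SLS found (no samples below ", threshold, " N)")
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  first <- runs[1L, ]
  n <- length(contra_grf$values)
  if (first$start == 1L || first$end == n) {
    stop("detect_sls: truncated SLS (below-threshold run touches the ",
         "series boundary; cannot certify the support window)")
  }
  tt <- series_times(contra_grf)
  structure(
    list(start_index = first$start, end_index = first$end,
         start_time = tt[first$start], end_time = tt[first$end],
         rate = contra_grf$rate, threshold = threshold,
         runs = runs, split_fraction = NULL, n_points = NULL,
         early = NULL, late = NULL),
    class = "sls_interval"
  )
}

#' @export
print.sls_interval <- function(x, ...) {
  cat(sprintf(
    "<sls_interval> samples %d..%d (t = %.3f..%.3f s, %.0f ms) below %g N\n",
    x$start_index, x$end_index, x$start_time, x$end_time,
    1000 * (x$end_time - x$start_time), x$threshold))
  if (!is.null(x$early)) {
    cat(sprintf("  early: grid points %d..%d, late: %d..%d (fraction %.2f)\n",
                x$early[1L] - 1L, x$early[2L] - 1L,
                x$late[1L] - 1L, x$late[2L] - 1L, x$split_fraction))
  }
  invisible(x)
}

#' Split a single-limb-support window into early and late segments
#'
#' Divides the time-normalized SLS window at `fraction` of its duration. On
#' an `n_points` normalization grid the boundary grid point belongs to both
#' segments, so at the default fraction 0.5 on a 101-point grid each segment
#' has 51 points (0-50 % and 50-100 %).
#'
#' @param interval `sls_interval` from [detect_sls()].
#' @param fraction Split point in (0, 1); default 0.5.
#' @param n_points Normalization grid size (default 101).
#' @return The interval with `early` and `late` populated as 1-based
#'   inclusive grid-index ranges, plus `split_fraction` and `n_points`.
#' @export
split_early_late <- function(interval, fraction = 0.5, n_points = 101L) {
  stopifnot(inherits(interval, "sls_interval"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("split_early_late: 'fraction' must lie strictly in (0, 1)")
  }
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("split_early_late: 'n_points' must be >= 3")
  boundary <- as.integer(round(fraction * (n_points - 1L)))
  boundary <- min(max(boundary, 1L), n_points - 2L)
  interval$split_fraction <- fraction
  interval$n_points <- n_points
  interval$early <- c(1L, boundary + 1L)
  interval$late <- c(boundary + 1L, n_points)
  interval
}

#' Time-normalize a series over a support window
#'
#' Linearly interpolates the series onto `n_points` equispaced times spanning
#' the interval (0-100 % of the window), the standard gait-analysis
#' normalization. The first and last output samples equal the series values
#' at the interval bounds, and the result is independent of the source
#' sampling rate for band-limited signals.
#'
#' @param series `uniform_series` covering the interval.
#' @param interval `sls_interval`.
#' @param n_points Grid size (default 101: 0-100 % in 1 % steps).
#' @param source Optional label recorded on the result.
#' @return Object of class `normalized_waveform`: `values` (length
#'   `n_points`), `grid` (0..100), `source`, `segment = "full"` and the
#'   window bounds.
#' @export
normalize_time <- function(series, interval, n_points = 101L, source = "") {
  stopifnot(inherits(series, "uniform_series"), inherits(interval, "sls_interval"))
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("normalize_time: 'n_points' must be >= 2")
  tt <- series_times(series)
  eps <- 1e-9
  if (interval$start_time < tt[1L] - eps ||
      interval$end_time > tt[length(tt)] + eps) {
    stop("normalize_time: interval [", interval$start_time, ", ",
         interval$end_time, "] s lies outside the series time range")
  }
  xout <- seq(interval$start_time, interval$end_time, length.out = n_points)
  y <- stats::approx(tt, series$values, xout = xout, rule = 2)$y
  structure(
    list(values = y,
         grid = seq(0, 100, length.out = n_points),
         source = source, segment = "full",
         start_time = interval$start_time, end_time = interval$end_time),
    class = "normalized_waveform"
  )
}

#' @export
print.normalized_waveform <- function(x, ...) {
  cat(sprintf("<normalized_waveform> %d points (%s, %s): %.3f..%.3f\n",
              length(x$values),
              if (nzchar(x$source)) x$source else "unlabeled",
              x$segment, min(x$values), max(x$values)))
  invisible(x)
}

#' Spatiotemporal gait parameters from contact events
#'
#' Event-based estimates of walking speed, step length and step rate from
#' ordered alternating foot-contact times and (optionally) the forward
#' positions of the contacts.
#'
#' @param event_times Ordered contact times in seconds (>= 3 events).
#' @param forward_positions Optional forward positions in m at those events.
#' @return List with `step_rate` (steps/min), and, when positions are given,
#'   `step_length` (m) and `walking_speed` (m/s).
#' @examples
#' spatiotemporal(c(0, 0.5, 1.0, 1.5), c(0, 0.6, 1.2, 1.8))
#' @export
spatiotemporal <- function(event_times, forward_positions = NULL) {
  event_times <- as.numeric(event_times)
  if (length(event_times) < 3L) {
    stop("spatiotemporal: need at least 3 contact events, got ",
         length(event_times))
  }
  if (is.unsorted(event_times, strictly = TRUE)) {
    stop("spatiotemporal: 'event_times' must be strictly increasing")
  }
  n_steps <- length(event_times) - 1L
  elapsed <- event_times[length(event_times)] - event_times[1L]
  out <- list(step_rate = 60 * n_steps / elapsed)
  if (!is.null(forward_positions)) {
    forward_positions <- as.numeric(forward_positions)
    if (length(forward_positions) != length(event_times)) {
      stop("spatiotemporal: 'forward_positions' must match 'event_times'")
    }
    out$step_length <- mean(diff(forward_positions))
    out$walking_speed <-
      (forward_positions[length(forward_positions)] - forward_positions[1L]) /
      elapsed
  }
  out
}
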