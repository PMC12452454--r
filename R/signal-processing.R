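#' Zero-phase low-pass Butterworth filter
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase,
#' no time shift). The effective magnitude response is the square of the
#' single-pass response, so attenuation at the cutoff is -6 dB (amplitude
#' factor 0.5) rather than the single-pass -3 dB. Edge transients are
#' controlled by odd-reflection padding of length `3 * order` samples at each
#' end together with steady-state initial conditions, so a constant signal
#' passes through unchanged (DC gain 1).
#'
#' Default cutoffs used elsewhere in the package: 10 Hz for vertical
#' acceleration and force-plate GRF, 12 Hz for angular velocity.
#'
#' @param series A [uniform_series()].
#' @param cutoff_hz Cutoff frequency in Hz; must lie strictly below the
#'   Nyquist frequency `rate / 2`.
#' @param order Filter order of each pass (default 4).
#' @return A filtered `uniform_series` with the same rate, length, units and
#'   start time.
#' @examples
#' s <- uniform_series(rep(5, 400), rate = 200, units = "N")
#' f <- lowpass(s, cutoff_hz = 10)
#' max(abs(f$values - 5)) # ~0: DC gain is exactly 1
#' @export
lowpass <- function(series, cutoff_hz, order = 4L) {
  stopifnot(inherits(series, "uniform_series"))
  nyq <- series$rate / 2
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L ||
      !is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop("lowpass: 'cutoff_hz' must lie in (0, ", nyq,
         ") Hz (Nyquist for rate ", series$rate, " Hz)")
  }
  order <- as.integer(order)
  if (order < 1L) stop("lowpass: 'order' must be >= 1")
  x <- series$values
  n <- length(x)
  pad <- 3L * order
  if (n <= pad) {
    stop("lowpass: series too short for edge padding; need at least ",
         pad + 1L, " samples, got ", n)
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  y <- filtfilt_padded(bf$b, bf$a, x, pad)
  uniform_series(y, rate = series$rate, units = series$units, t0 = series$t0)
}

# Forward-backward IIR filtering with odd-reflection padding and
# steady-state (constant-signal) initial conditions at each pass.
filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  left  <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  one_pass <- function(v) {
    k <- max(length(a), length(b)) - 1L
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(v[1], k), init.y = rep(v[1], k)))
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Resample a uniform series by linear interpolation
#'
#' Interpolates the series onto a new uniform grid at `new_rate` spanning the
#' same time interval. The first sample (and, when the old and new rates are
#' commensurate, the last) is preserved exactly. Linear interpolation is exact
#' on linear ramps and accurate for signals band-limited well below the new
#' Nyquist frequency; it is used in this package to put 200 Hz IMU streams and
#' 100 Hz force-plate streams onto one timeline.
#'
#' @param series A [uniform_series()].
#' @param new_rate Target sampling rate in Hz (> 0).
#' @return A `uniform_series` at `new_rate`.
#' @export
resample_series <- function(series, new_rate) {
  stopifnot(inherits(series, "uniform_series"))
  if (!is.numeric(new_rate) || length(new_rate) != 1L ||
      !is.finite(new_rate) || new_rate <= 0) {
    stop("resample_series: 'new_rate' must be a single positive number (Hz)")
  }
  n <- length(series$values)
  if (n == 1L) {
    return(uniform_series(series$values, rate = new_rate,
                          units = series$units, t0 = series$t0))
  }
  span <- (n - 1) / series$rate
  m <- floor(span * new_rate + 1e-9) + 1
  new_t <- series$t0 + (seq_len(m) - 1) / new_rate
  old_t <- series_times(series)
  y <- stats::approx(old_t, series$values, xout = new_t, rule = 2)$y
  uniform_series(y, rate = new_rate, units = series$units, t0 = series$t0)
}
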