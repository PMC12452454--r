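#' Uniformly sampled scalar signal
#'
#' The basic container used throughout the package: an ordered vector of
#' finite samples taken at a constant rate. Sample `i` (1-based) is taken at
#' time `t0 + (i - 1) / rate` seconds.
#'
#' @param values Numeric vector of samples; all finite, length >= 1.
#' @param rate Sampling frequency in Hz (> 0).
#' @param units Unit label, e.g. `"N"`, `"deg"`, `"g"`, `"m"`, `"N.m"`.
#' @param t0 Time of the first sample in seconds.
#'
#' @return An object of class `uniform_series`.
#' @examples
#' s <- uniform_series(sin(2 * pi * 2 * (0:199) / 200), rate = 200, units = "g")
#' n_samples(s)
#' @export
uniform_series <- function(values, rate, units = "", t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("uniform_series: 'values' must contain at least one sample")
  }
  if (!all(is.finite(values))) {
    stop("uniform_series: all samples must be finite (first bad index: ",
         which(!is.finite(values))[1L], ")")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("uniform_series: 'rate' must be a single positive number (Hz)")
  }
  structure(
    list(values = values, rate = as.numeric(rate),
         units = as.character(units), t0 = as.numeric(t0)),
    class = "uniform_series"
  )
}

#' Number of samples in a uniform series
#' @param x A `uniform_series`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  length(x$values)
}

#' Sample times of a uniform series
#' @param x A `uniform_series`.
#' @return Numeric vector of times in seconds, one per sample.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_along(x$values) - 1) / x$rate
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz [%s], t = %.4f..%.4f s\n",
              length(x$values), x$rate,
              if (nzchar(x$units)) x$units else "unitless",
              x$t0, x$t0 + (length(x$values) - 1) / x$rate))
  invisible(x)
}

#' @export
as.data.frame.uniform_series <- function(x, ...) {
  data.frame(time = series_times(x), value = x$values)
}

# internal: elementwise combination preserving rate/t0, checking alignment
series_align_check <- function(a, b, what = "series") {
  stopifnot(inherits(a, "uniform_series"), inherits(b, "uniform_series"))
  if (length(a$values) != length(b$values)) {
    stop(what, ": length mismatch (", length(a$values), " vs ",
         length(b$values), ")")
  }
  if (abs(a$rate - b$rate) > 1e-9 * a$rate) {
    stop(what, ": sampling-rate mismatch (", a$rate, " vs ", b$rate, " Hz)")
  }
  if (abs(a$t0 - b$t0) > 1e-9) {
    stop(what, ": start-time mismatch")
  }
  invisible(TRUE)
}
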