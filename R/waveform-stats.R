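#' Coefficient of multiple correlation (CMC)
#'
#' Waveform-pattern similarity index for a set of F waveforms of T frames
#' each (within-day form). With `Y_ft` the value of waveform f at frame t,
#' `Ybar_t` the across-waveform mean at frame t and `Ybar` the grand mean:
#'
#' \deqn{CMC = \sqrt{1 - \frac{\sum_f \sum_t (Y_{ft} - \bar{Y}_t)^2 / (T(F-1))}
#'                        {\sum_f \sum_t (Y_{ft} - \bar{Y})^2 / (FT-1)}}}
#'
#' When the waveforms differ mainly by a vertical offset the within-frame
#' mean square exceeds the total mean square, the radicand is negative, and
#' the CMC is a complex number: such results are reported as `NaN` (never
#' silently clipped to 0), mirroring how they are tabulated in gait studies.
#'
#' @param waveforms Numeric F x T matrix (one row per waveform), or a list of
#'   equal-length numeric vectors. F >= 2, T >= 2, all values finite.
#' @param segment Label recorded on the result (default `"full"`).
#' @return Object of class `cmc_result`: `value` in \[0, 1\] or `NaN`,
#'   `is_nan`, `category` (see [categorize_cmc()]) and `segment`.
#' @examples
#' cmc(rbind(c(0, 1, 2, 3), c(0.1, 1.1, 2.1, 3.1)))  # 0.99825
#' cmc(rbind(c(0, 1, 2), c(2, 1, 0)))                # NaN (complex radicand)
#' @export
cmc <- function(waveforms, segment = "full") {
  if (is.list(waveforms)) {
    lens <- lengths(waveforms)
    if (length(unique(lens)) != 1L) {
      stop("cmc: all waveforms must have equal length (got ",
           paste(lens, collapse = ", "), ")")
    }
    waveforms <- do.call(rbind, waveforms)
  }
  Y <- as.matrix(waveforms)
  F_ <- nrow(Y); T_ <- ncol(Y)
  if (F_ < 2L) stop("cmc: need at least 2 waveforms")
  if (T_ < 2L) stop("cmc: need at least 2 frames per waveform")
  if (!all(is.finite(Y))) stop("cmc: non-finite input value")

  frame_means <- colMeans(Y)
  grand_mean <- mean(Y)
  within_ms <- sum(sweep(Y, 2L, frame_means)^2) / (T_ * (F_ - 1L))
  total_ms <- sum((Y - grand_mean)^2) / (F_ * T_ - 1L)
  if (total_ms == 0) {
    # all waveforms identical and constant: perfect agreement
    value <- 1
  } else {
    ratio <- within_ms / total_ms
    value <- if (ratio > 1) NaN else sqrt(1 - ratio)
  }
  new_cmc_result(value, segment)
}

new_cmc_result <- function(value, segment) {
  structure(
    list(value = value, is_nan = is.nan(value),
         category = categorize_cmc(value), segment = segment),
    class = "cmc_result"
  )
}

#' @export
print.cmc_result <- function(x, ...) {
  cat(sprintf("<cmc_result> %s = %s (%s)\n", x$segment,
              if (x$is_nan) "NaN" else sprintf("%.4f", x$value), x$category))
  invisible(x)
}

#' Categorize a CMC value
#'
#' Similarity bands used for gait-waveform comparison: moderate
#' \[0.65, 0.75), good \[0.75, 0.85), very good \[0.85, 0.95), excellent
#' \[0.95, 1\]; values below 0.65 indicate no clear similarity ("none").
#' Intervals are half-open with boundary ties assigned to the upper band.
#' `NaN` (complex radicand) is kept as its own category rather than folded
#' into "none".
#'
#' @param value CMC value in \[0, 1\], or `NaN`.
#' @return One of `"none"`, `"moderate"`, `"good"`, `"very_good"`,
#'   `"excellent"`, `"NaN"`.
#' @export
categorize_cmc <- function(value) {
  if (length(value) != 1L) stop("categorize_cmc: 'value' must be scalar")
  if (is.nan(value)) return("NaN")
  if (!is.numeric(value) || value < 0 || value > 1) {
    stop("categorize_cmc: value ", value, " outside [0, 1] and not NaN")
  }
  if (value >= 0.95) "excellent"
  else if (value >= 0.85) "very_good"
  else if (value >= 0.75) "good"
  else if (value >= 0.65) "moderate"
  else "none"
}

#' CMC over an early or late segment of normalized waveforms
#'
#' Restricts two waveforms on the same normalization grid to the early or
#' late segment of the support window (boundary point included in both) and
#' applies [cmc()].
#'
#' @param a,b [normalize_time()] results on identical grids.
#' @param segment `"early"` or `"late"`.
#' @param fraction Early/late split point (default 0.5).
#' @return A `cmc_result` labeled with the segment.
#' @export
cmc_segment <- function(a, b, segment = c("early", "late"), fraction = 0.5) {
  segment <- match.arg(segment)
  stopifnot(inherits(a, "normalized_waveform"), inherits(b, "normalized_waveform"))
  n <- length(a$values)
  if (length(b$values) != n || max(abs(a$grid - b$grid)) > 1e-9) {
    stop("cmc_segment: waveforms are on different normalization grids")
  }
  if (fraction <= 0 || fraction >= 1) {
    stop("cmc_segment: 'fraction' must lie strictly in (0, 1)")
  }
  boundary <- as.integer(round(fraction * (n - 1L)))
  boundary <- min(max(boundary, 1L), n - 2L)
  idx <- if (segment == "early") 1L:(boundary + 1L) else (boundary + 1L):n
  cmc(rbind(a$values[idx], b$values[idx]), segment = segment)
}

#' Tabulate CMC results
#'
#' Builds the per-trial / per-segment results table used by
#' [write_report()]: one row per `cmc_result` with its value and category.
#'
#' @param results Named or unnamed list of `cmc_result` objects.
#' @param condition,trial Optional vectors (recycled) labeling each row.
#' @return A data frame with columns `condition`, `trial`, `segment`,
#'   `cmc`, `category`.
#' @export
cmc_table <- function(results, condition = NA_character_, trial = NA_integer_) {
  if (inherits(results, "cmc_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, TRUE, "cmc_result")))
  data.frame(
    condition = rep_len(as.character(condition), length(results)),
    trial = rep_len(trial, length(results)),
    segment = vapply(results, function(r) r$segment, character(1)),
    cmc = vapply(results, function(r) r$value, numeric(1)),
    category = vapply(results, function(r) r$category, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Summarize a CMC table by condition and segment
#'
#' Computes, per condition x segment cell, the minimum and maximum CMC over
#' numeric trials, the number of trials at or above 0.65 (at least moderate
#' similarity), the number below 0.65, and the number of NaN (complex
#' radicand) trials -- the summary layout used to report waveform-similarity
#' ranges across cadence conditions.
#'
#' @param tab Data frame with columns `condition`, `segment`, `cmc` (NaN
#'   allowed), e.g. from [cmc_table()] or [read_reference_cmc()].
#' @return Data frame with one row per condition x segment:
#'   `n`, `n_nan`, `n_below_0.65`, `n_moderate_plus`, `min_cmc`, `max_cmc`
#'   (min/max over non-NaN values; NA when all are NaN).
#' @export
summarize_cmc_table <- function(tab) {
  stopifnot(all(c("condition", "segment", "cmc") %in% names(tab)))
  split_by <- interaction(tab$condition, tab$segment, drop = TRUE)
  rows <- lapply(split(tab, split_by), function(d) {
    v <- d$cmc
    ok <- !is.nan(v)
    data.frame(
      condition = d$condition[1L], segment = d$segment[1L],
      n = length(v), n_nan = sum(!ok),
      n_below_0.65 = sum(ok & v < 0.65),
      n_moderate_plus = sum(ok & v >= 0.65),
      min_cmc = if (any(ok)) min(v[ok]) else NA_real_,
      max_cmc = if (any(ok)) max(v[ok]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
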