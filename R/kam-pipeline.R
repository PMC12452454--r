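STANDARD_GRAVITY <- 9.80665  # m/s^2

#' Subject parameters for KAM estimation
#'
#' @param body_mass Body mass in kg (> 0).
#' @param shank_length Shank length in m, typically obtained from optical
#'   motion analysis; sanity band (0.2, 0.7) m.
#' @param initial_sta Initial frontal-plane shank tilt angle in degrees used
#'   to anchor the IMU-derived tilt to an externally measured value at
#'   calibration (default 0).
#' @return Object of class `subject_parameters` with `body_weight` in N
#'   computed as `body_mass * 9.80665`.
#' @examples
#' subject_parameters(body_mass = 64, shank_length = 0.39, initial_sta = 3)
#' @export
subject_parameters <- function(body_mass, shank_length, initial_sta = 0) {
  if (!is.numeric(body_mass) || body_mass <= 0) {
    stop("subject_parameters: 'body_mass' must be > 0 kg")
  }
  if (!is.numeric(shank_length) || shank_length <= 0.2 || shank_length >= 0.7) {
    stop("subject_parameters: 'shank_length' ", shank_length,
         " m outside sanity band (0.2, 0.7) m")
  }
  structure(
    list(body_mass = as.numeric(body_mass),
         body_weight = as.numeric(body_mass) * STANDARD_GRAVITY,
         shank_length = as.numeric(shank_length),
         initial_sta = as.numeric(initial_sta)),
    class = "subject_parameters"
  )
}

#' Pipeline configuration
#'
#' Default values reproduce the settings of the estimation method: 10 Hz
#' low-pass cutoff for the vertical acceleration and force-plate GRF, 12 Hz
#' for angular velocity, a 10 N contralateral-GRF threshold for single-limb
#' support, a 0.5 early/late split of the normalized support window, and a
#' 101-point (0-100 % in 1 % steps) normalization grid. Set a cutoff to
#' `NULL` to bypass that filter (useful for noise-free validation runs).
#'
#' @param accel_cutoff_hz Low-pass cutoff for the vertical acceleration (Hz).
#' @param gyro_cutoff_hz Low-pass cutoff for angular velocity (Hz).
#' @param grf_cutoff_hz Low-pass cutoff for force-plate GRF (Hz).
#' @param filter_order Butterworth order per pass.
#' @param sls_threshold_n Contralateral vertical-GRF threshold in N.
#' @param split_fraction Early/late split point of the normalized SLS window.
#' @param n_points Samples on the normalization grid.
#' @param adduction_sign +1 (right-limb convention) or -1: sign applied to
#'   the frontal tilt deviation so that lean toward adduction is positive.
#' @param normalize_by_mass If `TRUE`, KAM is reported in N.m/kg.
#' @return Object of class `kam_config`.
#' @export
kam_config <- function(accel_cutoff_hz = 10, gyro_cutoff_hz = 12,
                       grf_cutoff_hz = 10, filter_order = 4L,
                       sls_threshold_n = 10, split_fraction = 0.5,
                       n_points = 101L, adduction_sign = 1,
                       normalize_by_mass = FALSE) {
  if (!(adduction_sign %in% c(-1, 1))) {
    stop("kam_config: 'adduction_sign' must be +1 or -1")
  }
  structure(
    list(accel_cutoff_hz = accel_cutoff_hz, gyro_cutoff_hz = gyro_cutoff_hz,
         grf_cutoff_hz = grf_cutoff_hz, filter_order = as.integer(filter_order),
         sls_threshold_n = sls_threshold_n, split_fraction = split_fraction,
         n_points = as.integer(n_points), adduction_sign = adduction_sign,
         normalize_by_mass = isTRUE(normalize_by_mass)),
    class = "kam_config"
  )
}

#' Vertical GRF surrogate from trunk acceleration
#'
#' Scales the globally resolved vertical specific force (gravity-inclusive,
#' in g) measured at the lower back by body weight:
#' `GRF_VT(t) = body_weight * a_vert(t)`. Quiet standing (`a_vert = 1 g`)
#' yields body weight exactly. Values are deliberately not clamped at zero.
#'
#' @param a_vert `uniform_series` in g from [global_vertical_accel()],
#'   low-pass filtered at 10 Hz in the default pipeline.
#' @param body_weight Body weight in N (> 0).
#' @return `uniform_series` in N.
#' @export
estimate_grf_vt <- function(a_vert, body_weight) {
  stopifnot(inherits(a_vert, "uniform_series"))
  if (!is.numeric(body_weight) || length(body_weight) != 1L || body_weight <= 0) {
    stop("estimate_grf_vt: 'body_weight' must be a single positive value (N)")
  }
  uniform_series(body_weight * a_vert$values, rate = a_vert$rate,
                 units = "N", t0 = a_vert$t0)
}

#' Frontal-plane shank tilt angle (FP-STA)
#'
#' Re-anchors the IMU-derived frontal tilt of the shank sensor with an
#' additive offset so that its value over the quiet-standing calibration
#' window equals an externally supplied initial angle:
#' `fp_sta(t) = sign * (frontal_tilt(t) - anchor) + initial_sta`, where
#' `anchor` is the mean frontal tilt over the calibration window (more robust
#' to noise than a single sample), or the first sample if no window is given.
#'
#' @param tilt `tilt_trajectory` of the shank (LLS) sensor.
#' @param initial_sta Initial shank tilt angle in degrees (e.g. from optical
#'   motion analysis at calibration).
#' @param cal_window Optional `c(start_s, end_s)` of the quiet-standing
#'   window on the trajectory's timeline.
#' @param sign +1 or -1 adduction-positive sign convention.
#' @return `uniform_series` in deg.
#' @export
estimate_fp_sta <- function(tilt, initial_sta, cal_window = NULL, sign = 1) {
  stopifnot(inherits(tilt, "tilt_trajectory"))
  ft <- tilt$frontal_tilt
  if (is.null(cal_window)) {
    anchor <- ft$values[1L]
  } else {
    tt <- series_times(ft)
    sel <- tt >= cal_window[1L] - 1e-9 & tt <= cal_window[2L] + 1e-9
    if (!any(sel)) stop("estimate_fp_sta: calibration window contains no samples")
    anchor <- mean(ft$values[sel])
  }
  uniform_series(sign * (ft$values - anchor) + initial_sta,
                 rate = ft$rate, units = "deg", t0 = ft$t0)
}

#' Frontal-plane lever arm
#'
#' `lever(t) = shank_length * sin(fp_sta(t))`, the horizontal frontal-plane
#' offset between the GRF line of action and the knee implied by the shank
#' tilt.
#'
#' @param fp_sta `uniform_series` in deg from [estimate_fp_sta()].
#' @param shank_length Shank length in m (> 0).
#' @return `uniform_series` in m.
#' @export
compute_lever_arm <- function(fp_sta, shank_length) {
  stopifnot(inherits(fp_sta, "uniform_series"))
  if (!is.numeric(shank_length) || shank_length <= 0) {
    stop("compute_lever_arm: 'shank_length' must be > 0 m")
  }
  uniform_series(shank_length * sin(fp_sta$values * pi / 180),
                 rate = fp_sta$rate, units = "m", t0 = fp_sta$t0)
}

#' Knee adduction moment from GRF and lever arm
#'
#' Elementwise product `KAM(t) = GRF_VT(t) * lever(t)` in N.m, optionally
#' normalized by body mass to N.m/kg.
#'
#' @param grf_vt `uniform_series` in N.
#' @param lever `uniform_series` in m, same rate/length/start.
#' @param body_mass Optional body mass in kg for normalization.
#' @return `uniform_series` in N.m (or N.m/kg).
#' @export
estimate_kam <- function(grf_vt, lever, body_mass = NULL) {
  series_align_check(grf_vt, lever, "estimate_kam")
  v <- grf_vt$values * lever$values
  units <- "N.m"
  if (!is.null(body_mass)) {
    if (body_mass <= 0) stop("estimate_kam: 'body_mass' must be > 0 kg")
    v <- v / body_mass
    units <- "N.m/kg"
  }
  uniform_series(v, rate = grf_vt$rate, units = units, t0 = grf_vt$t0)
}

#' Run the full two-IMU KAM estimation pipeline
#'
#' Chains the estimation stages: angular-velocity filtering, quiet-standing
#' static calibration, gyroscope orientation propagation, resolution of the
#' trunk acceleration into the global vertical, vertical-GRF scaling by body
#' weight, frontal shank-tilt anchoring, lever-arm computation, and the final
#' GRF x lever-arm product. All four linked waveforms are returned on the
#' common 200 Hz IMU timeline.
#'
#' @param l3 [imu_recording()] of the lower-back sensor.
#' @param lls [imu_recording()] of the lower-lateral-shank sensor.
#' @param subject [subject_parameters()].
#' @param config [kam_config()].
#' @return Object of class `kam_estimate`: list with `uniform_series`
#'   elements `grf_vt` (N), `fp_sta` (deg), `lever_arm` (m), `kam` (N.m or
#'   N.m/kg), plus `subject` and `config` echoes.
#' @export
run_kam_pipeline <- function(l3, lls, subject, config = kam_config()) {
  stopifnot(inherits(subject, "subject_parameters"),
            inherits(config, "kam_config"))
  for (rec in list(l3, lls)) {
    if (!inherits(rec, "imu_recording")) {
      stop("read: inputs must be imu_recording objects")
    }
    if (nrow(rec$accel) == 0L) stop("read: zero-length recording")
    if (is.null(rec$calibration_window)) {
      stop("calibration: recording has no quiet-standing calibration window")
    }
  }

  filt3 <- function(m, cutoff, rate, t0) {
    if (is.null(cutoff)) return(m)
    apply(m, 2L, function(col) {
      lowpass(uniform_series(col, rate, t0 = t0), cutoff,
              config$filter_order)$values
    })
  }

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(stage, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  process_sensor <- function(rec) {
    gyro_f <- with_stage("filter",
      filt3(rec$gyro, config$gyro_cutoff_hz, rec$rate, rec$t0))
    cw <- rec$calibration_window
    idx <- which(rec_times(rec) >= cw[1L] - 1e-9 & rec_times(rec) <= cw[2L] + 1e-9)
    if (length(idx) == 0L) stop("calibration: empty calibration window")
    q0 <- with_stage("calibration",
      static_calibration(rec$accel[idx, , drop = FALSE], rec$frame_map,
                         rate = rec$rate))
    tilt <- with_stage("propagation",
      propagate_orientation(gyro_f, q0, rate = rec$rate, t0 = rec$t0))
    list(tilt = tilt)
  }

  l3_s <- process_sensor(l3)
  lls_s <- process_sensor(lls)

  a_vert <- with_stage("vertical_resolution",
    global_vertical_accel(l3$accel, l3_s$tilt, t0 = l3$t0))
  if (!is.null(config$accel_cutoff_hz)) {
    a_vert <- with_stage("filter",
      lowpass(a_vert, config$accel_cutoff_hz, config$filter_order))
  }
  grf_vt <- with_stage("grf_vt", estimate_grf_vt(a_vert, subject$body_weight))
  fp_sta <- with_stage("fp_sta",
    estimate_fp_sta(lls_s$tilt, subject$initial_sta,
                    cal_window = lls$calibration_window,
                    sign = config$adduction_sign))
  lever <- with_stage("lever_arm", compute_lever_arm(fp_sta, subject$shank_length))
  kam <- with_stage("kam",
    estimate_kam(grf_vt, lever,
                 body_mass = if (config$normalize_by_mass) subject$body_mass))

  structure(
    list(grf_vt = grf_vt, fp_sta = fp_sta, lever_arm = lever, kam = kam,
         subject = subject, config = config),
    class = "kam_estimate"
  )
}

#' @export
print.kam_estimate <- function(x, ...) {
  cat(sprintf(
    "<kam_estimate> %d samples @ %g Hz; KAM %.2f..%.2f %s; peak GRF-VT %.1f N\n",
    n_samples(x$kam), x$kam$rate, min(x$kam$values), max(x$kam$values),
    x$kam$units, max(x$grf_vt$values)))
  invisible(x)
}
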