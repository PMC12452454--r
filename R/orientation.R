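#' Sensor-to-global axis map
#'
#' Describes how a sensor's X/Y/Z axes are nominally aligned with the global
#' coordinate system. The global frame used throughout the package is
#' X = mediolateral, Y = anteroposterior, Z = vertical (up). The map is a
#' signed permutation matrix `R` (orthonormal, determinant +1) such that
#' `v_global = R %*% v_sensor`.
#'
#' Defaults match the two placements used by the estimation method:
#' * `"L3"` (lower back): sensor X mediolateral, Y vertical, Z anteroposterior.
#' * `"LLS"` (lower lateral shank): sensor X anteroposterior, Y vertical,
#'   Z mediolateral.
#'
#' The sign of one axis in the L3 default is chosen so the mapping is a
#' proper (right-handed) rotation; tilt angles are unaffected by that choice.
#'
#' @param placement `"L3"` or `"LLS"`.
#' @param axis_to_global Optional 3x3 signed permutation matrix overriding the
#'   default for the placement.
#' @return An object of class `sensor_frame_map` with elements `placement`
#'   and `R`.
#' @export
sensor_frame_map <- function(placement = c("L3", "LLS"), axis_to_global = NULL) {
  placement <- match.arg(placement)
  if (is.null(axis_to_global)) {
    R <- switch(placement,
      # columns = global image of sensor X, Y, Z
      L3  = cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)),
      LLS = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
    )
  } else {
    R <- axis_to_global
  }
  R <- unname(as.matrix(R))
  if (!all(dim(R) == c(3L, 3L))) {
    stop("sensor_frame_map: 'axis_to_global' must be a 3x3 matrix")
  }
  if (max(abs(t(R) %*% R - diag(3))) > 1e-9) {
    stop("sensor_frame_map: axis map must be orthonormal (signed permutation)")
  }
  if (abs(det(R) - 1) > 1e-9) {
    stop("sensor_frame_map: axis map must be a proper rotation (det +1)")
  }
  structure(list(placement = placement, R = R), class = "sensor_frame_map")
}

#' @export
print.sensor_frame_map <- function(x, ...) {
  cat(sprintf("<sensor_frame_map> placement %s\n", x$placement))
  print(x$R)
  invisible(x)
}

# sensor axis that is nominally vertical, expressed in the sensor frame
frame_map_up_in_sensor <- function(frame_map) {
  as.numeric(t(frame_map$R) %*% c(0, 0, 1))
}

#' Quiet-standing static calibration
#'
#' Estimates the initial sensor orientation from an accelerometer window
#' recorded during quiet standing, when the accelerometer measures only
#' gravity (+1 g along the global vertical). The returned orientation rotates
#' the mean measured gravity direction onto the global vertical; the
#' unobservable heading (rotation about the vertical) is fixed to the nominal
#' heading of the frame map.
#'
#' @param accel_window Numeric n x 3 matrix of accelerometer samples in g
#'   (sensor frame), covering at least 0.5 s.
#' @param frame_map A [sensor_frame_map()].
#' @param rate Sampling rate of the window in Hz (used only to enforce the
#'   minimum window duration).
#' @return A unit quaternion (numeric length 4, scalar first) rotating sensor
#'   to global coordinates, with the frame map attached as attribute
#'   `frame_map`.
#' @export
static_calibration <- function(accel_window, frame_map, rate = 200) {
  accel_window <- as.matrix(accel_window)
  if (ncol(accel_window) != 3L) {
    stop("static_calibration: 'accel_window' must have 3 columns (g)")
  }
  if (nrow(accel_window) < ceiling(0.5 * rate)) {
    stop("static_calibration: window must cover at least 0.5 s (",
         ceiling(0.5 * rate), " samples at ", rate, " Hz), got ",
         nrow(accel_window))
  }
  stopifnot(inherits(frame_map, "sensor_frame_map"))
  m <- colMeans(accel_window)
  mag <- sqrt(sum(m * m))
  if (mag < 0.9 || mag > 1.1) {
    stop("static_calibration: subject not static (mean acceleration ",
         "magnitude ", signif(mag, 4), " g outside [0.9, 1.1] g)")
  }
  u <- m / mag                       # measured up-direction, sensor frame
  u0 <- frame_map_up_in_sensor(frame_map)  # nominal up-direction
  axis <- crossprod3(u, u0)
  angle <- atan2(sqrt(sum(axis * axis)), sum(u * u0))
  q_corr <- quat_from_axis_angle(axis, angle)  # minimal tilt correction
  q0 <- quat_from_matrix(frame_map$R)
  q <- quat_normalize(quat_multiply(q0, q_corr))
  attr(q, "frame_map") <- frame_map
  q
}

#' Propagate orientation from gyroscope data
#'
#' Integrates body-frame angular velocity from an initial orientation,
#' producing a unit quaternion per sample and the frontal- and sagittal-plane
#' tilt angles of the sensor's nominally vertical axis. One quaternion
#' exponential update is applied per sample, with the per-step rotation
#' increment obtained from a cubic (4-point) quadrature of the sampled rates;
#' the quaternion is renormalized every step. No accelerometer or magnetometer
#' correction is applied during movement, so gyroscope bias accumulates as a
#' linear tilt drift (about `bias * t` degrees after `t` seconds).
#'
#' @param gyro Numeric n x 3 matrix of angular velocity in deg/s (sensor
#'   frame), or a list of three [uniform_series()]. Should be low-pass
#'   filtered (12 Hz default elsewhere in the package) beforehand.
#' @param initial Unit quaternion from [static_calibration()] (or any unit
#'   quaternion with a `frame_map` attribute / with `frame_map` supplied).
#' @param rate Sampling rate in Hz; taken from the series when `gyro` is a
#'   list of `uniform_series`.
#' @param frame_map Optional [sensor_frame_map()]; defaults to the one
#'   attached to `initial`.
#' @param t0 Start time in seconds of the first sample.
#' @return An object of class `tilt_trajectory`: list with `quat` (n x 4
#'   matrix), `frontal_tilt` and `sagittal_tilt` (`uniform_series` in deg),
#'   `rate` and `frame_map`. Frontal tilt is the inclination of the sensor's
#'   vertical axis projected on the frontal (mediolateral-vertical) plane;
#'   it is 0 when that axis is globally vertical, and positive when gravity
#'   tips toward the sensor's + frontal axis (the sign a static accelerometer
#'   reading `asin(a_frontal)` reports).
#' @export
propagate_orientation <- function(gyro, initial, rate = NULL,
                                  frame_map = NULL, t0 = 0) {
  if (is.list(gyro) && all(vapply(gyro, inherits, TRUE, "uniform_series"))) {
    if (is.null(rate)) rate <- gyro[[1]]$rate
    t0 <- gyro[[1]]$t0
    gyro <- cbind(gyro[[1]]$values, gyro[[2]]$values, gyro[[3]]$values)
  }
  gyro <- as.matrix(gyro)
  if (ncol(gyro) != 3L) stop("propagate_orientation: 'gyro' must have 3 columns")
  if (is.null(rate)) stop("propagate_orientation: 'rate' must be supplied")
  bad <- which(!is.finite(gyro))
  if (length(bad)) {
    stop("propagate_orientation: non-finite gyro sample at row ",
         ((bad[1L] - 1L) %% nrow(gyro)) + 1L)
  }
  if (is.null(frame_map)) frame_map <- attr(initial, "frame_map")
  if (is.null(frame_map)) {
    stop("propagate_orientation: no frame_map on 'initial'; supply one")
  }
  initial <- as.numeric(initial)
  if (abs(sqrt(sum(initial^2)) - 1) > 1e-6) {
    stop("propagate_orientation: 'initial' must be a unit quaternion")
  }

  n <- nrow(gyro)
  dt <- 1 / rate
  w <- gyro * (pi / 180)             # rad/s, body frame
  Q <- matrix(0, n, 4L)
  Q[1L, ] <- quat_normalize(initial)
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      if (k >= 2L && k <= n - 2L) {
        # integral of the cubic through samples k-1..k+2 over [t_k, t_k+1]
        dth <- dt / 24 * (-w[k - 1L, ] + 13 * w[k, ] + 13 * w[k + 1L, ] -
                            w[k + 2L, ])
      } else {
        dth <- dt / 2 * (w[k, ] + w[k + 1L, ])   # trapezoid at the ends
      }
      Q[k + 1L, ] <- quat_normalize(quat_multiply(Q[k, ], quat_exp(dth)))
    }
  }

  up_s <- frame_map_up_in_sensor(frame_map)
  v <- t(apply(Q, 1L, function(q) quat_rotate(q, up_s)))
  if (n == 1L) v <- matrix(v, 1L, 3L)
  frontal  <- atan2(-v[, 1L], v[, 3L]) * 180 / pi
  sagittal <- atan2(-v[, 2L], v[, 3L]) * 180 / pi

  structure(
    list(quat = Q,
         frontal_tilt = uniform_series(frontal, rate, units = "deg", t0 = t0),
         sagittal_tilt = uniform_series(sagittal, rate, units = "deg", t0 = t0),
         rate = rate, frame_map = frame_map),
    class = "tilt_trajectory"
  )
}

#' @export
print.tilt_trajectory <- function(x, ...) {
  cat(sprintf(
    "<tilt_trajectory> %d samples @ %g Hz (%s); frontal tilt %.2f..%.2f deg\n",
    nrow(x$quat), x$rate, x$frame_map$placement,
    min(x$frontal_tilt$values), max(x$frontal_tilt$values)))
  invisible(x)
}

#' Resolve measured acceleration into the global vertical
#'
#' Rotates each measured specific-force sample from the sensor frame into the
#' global frame using a tilt trajectory and returns the vertical (up)
#' component. During quiet standing this is 1 g.
#'
#' @param accel Numeric n x 3 matrix of accelerometer samples in g, or a list
#'   of three [uniform_series()].
#' @param tilt A `tilt_trajectory` from [propagate_orientation()] with the
#'   same length and rate.
#' @param t0 Start time (seconds) when `accel` is a matrix.
#' @return A `uniform_series` in g: the globally vertical specific force.
#' @export
global_vertical_accel <- function(accel, tilt, t0 = NULL) {
  stopifnot(inherits(tilt, "tilt_trajectory"))
  if (is.list(accel) && all(vapply(accel, inherits, TRUE, "uniform_series"))) {
    if (is.null(t0)) t0 <- accel[[1]]$t0
    accel <- cbind(accel[[1]]$values, accel[[2]]$values, accel[[3]]$values)
  }
  if (is.null(t0)) t0 <- tilt$frontal_tilt$t0
  accel <- as.matrix(accel)
  if (ncol(accel) != 3L) stop("global_vertical_accel: 'accel' must have 3 columns")
  if (nrow(accel) != nrow(tilt$quat)) {
    stop("global_vertical_accel: length mismatch (accel ", nrow(accel),
         ", tilt ", nrow(tilt$quat), ")")
  }
  out <- vapply(seq_len(nrow(accel)), function(i) {
    quat_rotate(tilt$quat[i, ], accel[i, ])[3L]
  }, numeric(1))
  uniform_series(out, rate = tilt$rate, units = "g", t0 = t0)
}
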