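test_that("default frame maps are proper signed permutations", {
  for (p in c("L3", "LLS")) {
    fm <- sensor_frame_map(p)
    expect_lt(max(abs(t(fm$R) %*% fm$R - diag(3))), 1e-12)
    expect_equal(det(fm$R), 1)
    # the sensor Y axis is nominally vertical for both placements
    expect_equal(as.numeric(fm$R %*% c(0, 1, 0)), c(0, 0, 1))
  }
  expect_error(sensor_frame_map("L3", axis_to_global = diag(c(1, 1, -1))),
               "proper rotation")
  expect_error(sensor_frame_map("L3", axis_to_global = matrix(1, 3, 3)),
               "orthonormal")
})

static_window <- function(v, n = 120) matrix(rep(v, each = n), ncol = 3)

test_that("static calibration recovers tilt from the gravity direction", {
  fm <- sensor_frame_map("L3")
  # level sensor: Y vertical, no tilt
  t0 <- propagate_orientation(matrix(0, 120, 3),
                              static_calibration(static_window(c(0, 1, 0)), fm),
                              rate = 200)
  expect_lt(abs(t0$frontal_tilt$values[1]), 1e-9)
  expect_lt(abs(t0$sagittal_tilt$values[1]), 1e-9)

  # 10 deg frontal-plane lean: gravity acquires a frontal-axis component
  a10 <- static_window(c(sin(10 * pi / 180), cos(10 * pi / 180), 0))
  t10 <- propagate_orientation(matrix(0, 120, 3),
                               static_calibration(a10, fm), rate = 200)
  expect_equal(t10$frontal_tilt$values[1], 10, tolerance = 1e-6)
  expect_lt(abs(t10$sagittal_tilt$values[1]), 1e-6)

  # non-static subject and too-short windows are rejected
  expect_error(static_calibration(static_window(c(0, 0.5, 0)), fm),
               "not static")
  expect_error(static_calibration(static_window(c(0, 1, 0), n = 50), fm),
               "0.5 s")
})

test_that("gyro propagation integrates single-axis rotations in closed form", {
  fm <- sensor_frame_map("L3", axis_to_global = diag(3))
  qi <- structure(c(1, 0, 0, 0), frame_map = fm)
  # all-zero gyro: constant orientation
  tz <- propagate_orientation(matrix(0, 300, 3), qi, rate = 200)
  expect_true(all(tz$frontal_tilt$values == tz$frontal_tilt$values[1]))
  # 10 deg/s about the mediolateral axis for 2 s -> 20 deg sagittal tilt
  g <- matrix(rep(c(10, 0, 0), each = 401), ncol = 3)
  ts <- propagate_orientation(g, qi, rate = 200)
  expect_equal(ts$sagittal_tilt$values[401], 20, tolerance = 0.01)
  expect_lt(max(abs(ts$frontal_tilt$values)), 1e-9)
  # quaternions stay unit norm
  expect_lt(max(abs(sqrt(rowSums(ts$quat^2)) - 1)), 1e-9)
  # non-finite samples are reported with their index
  g[57, 2] <- NA
  expect_error(propagate_orientation(g, qi, rate = 200), "row 57")
})

test_that("round trip through the simulator's gyro stays within 0.1 deg", {
  tr <- cached_trial(115)
  tilt <- propagate_orientation(
    tr$lls_imu$gyro,
    static_calibration(tr$lls_imu$accel[1:300, ], tr$lls_imu$frame_map),
    rate = tr$config$rate)
  expect_lt(max(abs(tilt$frontal_tilt$values - tr$truth$sta$values)), 0.1)
})

test_that("measured vertical specific force is 1 g for any static pose", {
  fm <- sensor_frame_map("L3")
  for (ang in c(0, 12, 30, 55)) {
    a <- static_window(c(sin(ang * pi / 180), cos(ang * pi / 180), 0))
    q <- static_calibration(a, fm)
    tilt <- propagate_orientation(matrix(0, nrow(a), 3), q, rate = 200)
    av <- global_vertical_accel(a, tilt)
    expect_equal(av$values, rep(1, nrow(a)), tolerance = 1e-9)
  }
  # a sensor pointing X straight up still reads 1 g after the signed
  # permutation is accounted for
  fmx <- sensor_frame_map("L3", axis_to_global = cbind(c(0, 0, 1), c(1, 0, 0),
                                                       c(0, 1, 0)))
  ax <- static_window(c(1, 0, 0))
  tx <- propagate_orientation(matrix(0, 120, 3),
                              static_calibration(ax, fmx), rate = 200)
  expect_equal(global_vertical_accel(ax, tx)$values, rep(1, 120))
  # tilted sensor with acceleration purely along its vertical axis: the
  # global vertical component is the cosine projection
  a30 <- static_window(c(sin(30 * pi / 180), cos(30 * pi / 180), 0))
  t30 <- propagate_orientation(matrix(0, 120, 3),
                               static_calibration(a30, fm), rate = 200)
  av30 <- global_vertical_accel(static_window(c(0, 1, 0)), t30)
  expect_equal(av30$values[1], cos(30 * pi / 180), tolerance = 1e-9)
  expect_error(global_vertical_accel(matrix(0, 10, 3), t30), "mismatch")
})

test_that("frontal and sagittal tilt do not depend on sensor yaw", {
  # remounting the sensor rotated about its own vertical axis changes the
  # initial quaternion and the body-frame gyro consistently; tilt angles
  # must not change (heading is unobservable)
  fm <- sensor_frame_map("LLS")
  tr <- cached_trial(115)
  gyro <- tr$lls_imu$gyro[1:600, ]
  q0 <- static_calibration(tr$lls_imu$accel[1:300, ], fm)
  ref <- propagate_orientation(gyro, q0, rate = 200)
  up_s <- as.numeric(t(fm$R) %*% c(0, 0, 1))
  set.seed(7)
  for (psi in runif(3, -pi, pi)) {
    qy <- imukam:::quat_from_axis_angle(up_s, psi)
    Rm <- cbind(imukam:::quat_rotate(qy, c(1, 0, 0)),
                imukam:::quat_rotate(qy, c(0, 1, 0)),
                imukam:::quat_rotate(qy, c(0, 0, 1)))
    q0p <- structure(imukam:::quat_multiply(as.numeric(q0), qy),
                     frame_map = fm)
    gyrop <- gyro %*% Rm   # rows: t(Rm) %*% omega
    alt <- propagate_orientation(gyrop, q0p, rate = 200)
    expect_lt(max(abs(alt$frontal_tilt$values - ref$frontal_tilt$values)), 1e-6)
    expect_lt(max(abs(alt$sagittal_tilt$values - ref$sagittal_tilt$values)), 1e-6)
  }
})

test_that("gyro bias produces at most linear tilt drift", {
  fm <- sensor_frame_map("L3", axis_to_global = diag(3))
  qi <- structure(c(1, 0, 0, 0), frame_map = fm)
  b <- 0.5  # deg/s
  n <- 1001 # 5 s at 200 Hz
  tilt <- propagate_orientation(matrix(rep(c(b, 0, 0), each = n), ncol = 3),
                                qi, rate = 200)
  t <- series_times(tilt$sagittal_tilt)
  total <- sqrt(tilt$sagittal_tilt$values^2 + tilt$frontal_tilt$values^2)
  expect_true(all(total <= b * t + 1e-6))
  expect_equal(total[n], b * 5, tolerance = 1e-3)
})
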