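test_that("subject parameters enforce the standard-gravity body weight", {
  s <- subject_parameters(64, 0.39, initial_sta = 3)
  expect_equal(s$body_weight, 64 * 9.80665, tolerance = 1e-9)
  expect_error(subject_parameters(-1, 0.4), "body_mass")
  expect_error(subject_parameters(70, 0.15), "sanity band")
  expect_error(subject_parameters(70, 0.9), "sanity band")
})

test_that("GRF-VT is the body-weight-scaled vertical specific force", {
  one_g <- uniform_series(rep(1, 10), 200, units = "g")
  expect_equal(estimate_grf_vt(one_g, 627.8)$values, rep(627.8, 10))
  zero_g <- uniform_series(rep(0, 10), 200, units = "g")
  expect_equal(estimate_grf_vt(zero_g, 627.8)$values, rep(0, 10))
  av <- uniform_series(c(1.2, 0.8), 200, units = "g")
  expect_equal(estimate_grf_vt(av, 600)$values, c(720, 480))
  expect_error(estimate_grf_vt(one_g, -5), "positive")
})

test_that("FP-STA re-anchors the frontal tilt additively", {
  mk_tilt <- function(frontal) {
    structure(list(
      quat = matrix(rep(c(1, 0, 0, 0), each = length(frontal)), ncol = 4),
      frontal_tilt = uniform_series(frontal, 200, units = "deg"),
      sagittal_tilt = uniform_series(frontal * 0, 200, units = "deg"),
      rate = 200, frame_map = sensor_frame_map("LLS")),
      class = "tilt_trajectory")
  }
  expect_equal(estimate_fp_sta(mk_tilt(rep(0, 5)), 4)$values, rep(4, 5))
  expect_equal(estimate_fp_sta(mk_tilt(c(2, 3, 5)), 4)$values, c(4, 5, 7))
  # mean-anchored over a calibration window
  fr <- c(1, 3, 10, 12)  # first two samples at t = 0, 1/200 s
  got <- estimate_fp_sta(mk_tilt(fr), 4, cal_window = c(0, 1 / 200))
  expect_equal(got$values, fr - 2 + 4)
  # sign convention flip
  expect_equal(estimate_fp_sta(mk_tilt(c(2, 3, 5)), 0, sign = -1)$values,
               c(0, -1, -3))
})

test_that("lever arm is shank_length * sin(FP-STA)", {
  deg <- function(v) uniform_series(v, 200, units = "deg")
  expect_equal(compute_lever_arm(deg(rep(0, 4)), 0.4)$values, rep(0, 4))
  expect_equal(compute_lever_arm(deg(90), 0.40)$values, 0.40)
  expect_equal(compute_lever_arm(deg(5), 0.40)$values, 0.034862,
               tolerance = 1e-5)
})

test_that("KAM is the elementwise GRF x lever product", {
  grf <- uniform_series(c(600, 650), 200, units = "N")
  lev <- uniform_series(c(0.03, 0.04), 200, units = "m")
  k <- estimate_kam(grf, lev)
  expect_equal(k$values, c(18, 26))
  expect_equal(k$units, "N.m")
  expect_equal(estimate_kam(grf, lev, body_mass = 65)$values, c(18, 26) / 65)
  short <- uniform_series(1, 200, units = "m")
  expect_error(estimate_kam(grf, short), "length mismatch")
})

test_that("KAM sign and scaling behave like a moment", {
  grf <- uniform_series(c(600, 620, 640), 200, units = "N")
  sta <- uniform_series(c(2, 4, 3), 200, units = "deg")
  sta_neg <- uniform_series(-sta$values, 200, units = "deg")
  k_pos <- estimate_kam(grf, compute_lever_arm(sta, 0.4))
  k_neg <- estimate_kam(grf, compute_lever_arm(sta_neg, 0.4))
  expect_equal(k_neg$values, -k_pos$values)        # sign flip is exact
  expect_true(all(k_pos$values > 0))
  # doubling body weight doubles KAM
  k2 <- estimate_kam(uniform_series(2 * grf$values, 200, units = "N"),
                     compute_lever_arm(sta, 0.4))
  expect_equal(k2$values, 2 * k_pos$values)
  # doubling shank length doubles KAM at small angles (sin linearity)
  k_l2 <- estimate_kam(grf, compute_lever_arm(sta, 0.8))
  expect_equal(k_l2$values, 2 * k_pos$values, tolerance = 0.005)
})

test_that("the full pipeline inverts the forward model without noise", {
  tr <- cached_trial(115)
  est <- estimate_trial(tr, passthrough_config())
  sls <- detect_sls(tr$contra_grf)
  tt <- series_times(est$kam)
  sel <- tt >= sls$start_time - 1e-9 & tt <= sls$end_time + 1e-9
  truth <- ground_truth_kam(tr)
  rel <- abs(est$kam$values[sel] - truth$values[sel]) / abs(truth$values[sel])
  expect_lt(max(rel), 1e-4)
  # the four waveforms share one timeline and satisfy the construction
  # identities exactly
  expect_equal(est$kam$values, est$grf_vt$values * est$lever_arm$values)
  expect_equal(est$lever_arm$values,
               tr$config$shank_length * sin(est$fp_sta$values * pi / 180))
})

test_that("pipeline errors carry the failing stage name", {
  tr <- cached_trial(115)
  subj <- trial_subject(tr)
  empty <- tr$l3_imu
  empty$accel <- empty$accel[0, , drop = FALSE]
  empty$gyro <- empty$gyro[0, , drop = FALSE]
  expect_error(run_kam_pipeline(empty, tr$lls_imu, subj), "read")
  nocal <- tr$l3_imu
  nocal$calibration_window <- NULL
  expect_error(run_kam_pipeline(nocal, tr$lls_imu, subj), "calibration")
})
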