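#' Synthetic gait simulation configuration
#'
#' Parameters of the forward gait model used as the package's validation bed.
#' Defaults emulate the cadence-controlled walking conditions the estimation
#' method targets (preferred 115, reduced 100, lowest 85 steps/min) with a
#' bimodal vertical-GRF shape; the unimodal option emulates the flattened GRF
#' seen at low step rates.
#'
#' @param cadence Step rate in steps/min (one of 115/100/85 in the study
#'   conditions; any positive value accepted).
#' @param n_strides Number of complete gait cycles simulated after the
#'   quiet-standing prefix.
#' @param body_mass Body mass in kg.
#' @param shank_length Shank length in m.
#' @param grf_shape `"bimodal"` (two peaks, midstance valley) or
#'   `"unimodal"`.
#' @param grf_peak_bw Peak amplitude of the stance GRF lobes in body-weight
#'   units (single value; bimodal valley is derived from it).
#' @param sta_amplitude Amplitude of the frontal shank-tilt excursion over
#'   stance in degrees.
#' @param initial_sta Quiet-standing frontal shank tilt in degrees.
#' @param accel_noise_sd Additive white accelerometer noise SD in g.
#' @param gyro_noise_sd Additive white gyroscope noise SD in deg/s.
#' @param seed Integer seed fixing all randomness of the trial.
#' @param rate IMU sampling rate in Hz.
#' @param grf_rate Force-plate sampling rate in Hz.
#' @param prefix_s Duration of the quiet-standing prefix in s.
#' @param blend_s Duration of the standing-to-gait cosine blend in s.
#' @param stance_fraction Stance duration as a fraction of the gait cycle.
#' @param double_support_fraction Duration of each double-support period as a
#'   fraction of the gait cycle.
#' @param step_length Forward distance per step in m (used for the event
#'   table only).
#' @return Object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(cadence = 115, n_strides = 4L, body_mass = 64,
                            shank_length = 0.39,
                            grf_shape = c("bimodal", "unimodal"),
                            grf_peak_bw = 1.10, sta_amplitude = 4,
                            initial_sta = 3, accel_noise_sd = 0.05,
                            gyro_noise_sd = 1, seed = 1L, rate = 200,
                            grf_rate = 100, prefix_s = 2, blend_s = 0.3,
                            stance_fraction = 0.6,
                            double_support_fraction = 0.1,
                            step_length = 0.62) {
  grf_shape <- match.arg(grf_shape)
  if (cadence <= 0) stop("gait_sim_config: 'cadence' must be > 0")
  if (accel_noise_sd < 0 || gyro_noise_sd < 0) {
    stop("gait_sim_config: noise SDs must be >= 0")
  }
  if (n_strides < 1L) stop("gait_sim_config: 'n_strides' must be >= 1")
  if (stance_fraction <= 0.5 || stance_fraction >= 1) {
    stop("gait_sim_config: 'stance_fraction' must lie in (0.5, 1)")
  }
  structure(
    list(cadence = cadence, n_strides = as.integer(n_strides),
         body_mass = body_mass, shank_length = shank_length,
         grf_shape = grf_shape, grf_peak_bw = grf_peak_bw,
         sta_amplitude = sta_amplitude, initial_sta = initial_sta,
         accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
         seed = as.integer(seed), rate = rate, grf_rate = grf_rate,
         prefix_s = prefix_s, blend_s = blend_s,
         stance_fraction = stance_fraction,
         double_support_fraction = double_support_fraction,
         step_length = step_length),
    class = "gait_sim_config"
  )
}

# raised cosine lobe on |s - center| < width/2, zero outside (C1 everywhere)
raised_cosine <- function(s, center, width) {
  out <- numeric(length(s))
  inside <- abs(s - center) < width / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * (s[inside] - center) / width))
  out
}

# C1 flat-top window: cosine rise over [0, r], 1 on [r, 1-r], cosine fall
stance_window <- function(s, r = 0.15) {
  out <- numeric(length(s))
  mid <- s >= r & s <= 1 - r
  lo <- s > 0 & s < r
  hi <- s > 1 - r & s < 1
  out[mid] <- 1
  out[lo] <- 0.5 * (1 - cos(pi * s[lo] / r))
  out[hi] <- 0.5 * (1 - cos(pi * (1 - s[hi]) / r))
  out
}

# per-foot stance GRF shape in body-weight units; s = stance fraction in [0,1]
grf_stance_shape <- function(s, shape = "bimodal", peak = 1.10) {
  w <- stance_window(s, r = 0.15)
  if (shape == "bimodal") {
    # two peaks near 25 / 75 % of stance with a midstance valley;
    # (peak + valley)/2 and (peak - valley)/2 parameterize the modulation
    valley <- peak - 0.34
    g <- (peak + valley) / 2 - (peak - valley) / 2 * cos(4 * pi * (s - 0.5))
    out <- w * g
  } else {
    inside <- s > 0 & s < 1
    out <- numeric(length(s))
    out[inside] <- peak * sin(pi * s[inside])^1.5
  }
  out[s <= 0 | s >= 1] <- 0
  out
}

# frontal shank-tilt bump over stance (0 at both stance edges, max 1 mid)
sta_bump <- function(s) {
  out <- numeric(length(s))
  inside <- s > 0 & s < 1
  out[inside] <- 0.5 * (1 - cos(2 * pi * s[inside]))
  out
}

# analytic d/ds of sta_bump
sta_bump_ds <- function(s) {
  out <- numeric(length(s))
  inside <- s > 0 & s < 1
  out[inside] <- pi * sin(2 * pi * s[inside])
  out
}

#' Simulate a synthetic gait trial
#'
#' Forward model producing ground-truth waveforms together with the sensor
#' streams the estimation pipeline consumes. The trial starts with a
#' quiet-standing prefix (both feet each carrying half body weight), blends
#' over `blend_s` seconds into steady-state periodic gait (right heel strike
#' at integer gait-cycle phase; the contralateral limb offset by half a
#' cycle), and runs for `n_strides` complete cycles.
#'
#' Construction:
#' * per-foot vertical GRF: body weight times a smooth stance shape
#'   ([raised-cosine / windowed lobes]), bimodal or unimodal;
#' * ground-truth GRF = total (both-feet) vertical force, which equals the
#'   stance-limb force throughout single support;
#' * trunk (L3) vertical specific force `a_vert = GRF / BW` in g; the L3
#'   sensor is held level so its sensor-frame acceleration is the frame-mapped
#'   `(0, a_vert, 0)`;
#' * frontal shank tilt: `initial_sta` plus a smooth `sta_amplitude` bump
#'   over each stance; the shank (LLS) gyroscope is the analytic derivative
#'   of that orientation and the LLS accelerometer reads the rotated gravity
#'   direction;
#' * ground-truth KAM = `GRF * shank_length * sin(STA)` at every sample (the
#'   construction identity);
#' * contralateral vertical GRF emitted at `grf_rate` (100 Hz) with the
#'   double-support overlap implied by the cadence;
#' * independent Gaussian noise added to every accelerometer (g) and
#'   gyroscope (deg/s) channel; all randomness derives from `seed`.
#'
#' @param config A [gait_sim_config()].
#' @return Object of class `synthetic_trial`: list with `truth` (list of
#'   `uniform_series`: `grf` N, `sta` deg, `kam` N.m, at the IMU rate),
#'   `l3_imu` and `lls_imu` ([imu_recording()]), `contra_grf`
#'   (`uniform_series`, N, at `grf_rate`), `events` (heel-strike/toe-off
#'   times and a contact table with forward positions) and the `config` echo.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  bw <- config$body_mass * STANDARD_GRAVITY
  cycle_t <- 2 * 60 / config$cadence          # stride (cycle) duration, s
  stance_t <- config$stance_fraction * cycle_t
  phase0 <- 0.5 + config$double_support_fraction / 2  # mid double support
  t_gait0 <- config$prefix_s
  t_end <- t_gait0 + (config$n_strides + 0.7 - phase0) * cycle_t

  # analytic signal generators, valid at any sampling instant -------------
  phase_at <- function(t) phase0 + (t - t_gait0) / cycle_t
  blend_w <- function(t) {
    w <- (t - t_gait0) / config$blend_s
    w <- pmin(pmax(w, 0), 1)
    0.5 * (1 - cos(pi * w))
  }
  foot_gait_grf <- function(t, offset) {   # per-foot, BW units; offset in cycles
    ph <- phase_at(t) - offset
    s <- (ph - floor(ph)) / config$stance_fraction
    grf_stance_shape(s, config$grf_shape, config$grf_peak_bw)
  }
  right_grf <- function(t) {
    w <- blend_w(t)
    bw * ((1 - w) * 0.5 + w * foot_gait_grf(t, 0))
  }
  left_grf <- function(t) {
    w <- blend_w(t)
    bw * ((1 - w) * 0.5 + w * foot_gait_grf(t, 0.5))
  }
  sta_deg <- function(t) {
    ph <- phase_at(t)
    s <- (ph - floor(ph)) / config$stance_fraction
    config$initial_sta + blend_w(t) * config$sta_amplitude * sta_bump(s)
  }
  sta_rate_deg_s <- function(t) {          # analytic d/dt of sta_deg
    ph <- phase_at(t)
    s <- (ph - floor(ph)) / config$stance_fraction
    dw <- ifelse(t > t_gait0 & t < t_gait0 + config$blend_s,
                 0.5 * pi / config$blend_s *
                   sin(pi * (t - t_gait0) / config$blend_s), 0)
    config$sta_amplitude *
      (dw * sta_bump(s) + blend_w(t) * sta_bump_ds(s) / stance_t)
  }

  # IMU-rate timeline ------------------------------------------------------
  n <- floor(t_end * config$rate) + 1L
  t <- (seq_len(n) - 1) / config$rate

  grf_truth <- right_grf(t) + left_grf(t)
  sta_truth <- sta_deg(t)
  kam_truth <- grf_truth * config$shank_length * sin(sta_truth * pi / 180)
  a_vert <- grf_truth / bw                  # g units

  l3_map <- sensor_frame_map("L3")
  lls_map <- sensor_frame_map("LLS")

  # L3 held level: sensor accel = R^T (0, 0, a_vert), gyro = 0
  l3_accel <- t(apply(cbind(0, 0, a_vert), 1L,
                      function(v) as.numeric(t(l3_map$R) %*% v)))
  l3_gyro <- matrix(0, n, 3L)

  # LLS rotated about the global anteroposterior axis by -sta(t), so the
  # measured frontal tilt (positive when gravity tips toward the sensor's
  # + frontal axis) equals sta; gravity in the sensor frame = R0^T R_y(sta) e_z
  sta_rad <- sta_truth * pi / 180
  grav_global <- cbind(sin(sta_rad), 0, cos(sta_rad))  # R_y(sta) e_z
  lls_accel <- t(apply(grav_global, 1L,
                       function(v) as.numeric(t(lls_map$R) %*% v)))
  # rotation axis (global AP) is the sensor axis mapped to anteroposterior
  ap_in_sensor <- as.numeric(t(lls_map$R) %*% c(0, 1, 0))
  lls_gyro <- outer(-sta_rate_deg_s(t), ap_in_sensor)

  if (config$accel_noise_sd > 0) {
    l3_accel <- l3_accel + matrix(stats::rnorm(3 * n, 0, config$accel_noise_sd), n)
    lls_accel <- lls_accel + matrix(stats::rnorm(3 * n, 0, config$accel_noise_sd), n)
  }
  if (config$gyro_noise_sd > 0) {
    l3_gyro <- l3_gyro + matrix(stats::rnorm(3 * n, 0, config$gyro_noise_sd), n)
    lls_gyro <- lls_gyro + matrix(stats::rnorm(3 * n, 0, config$gyro_noise_sd), n)
  }

  cal_win <- c(0.25, config$prefix_s - 0.25)
  l3_imu <- imu_recording(l3_accel, l3_gyro, rate = config$rate,
                          frame_map = l3_map, calibration_window = cal_win)
  lls_imu <- imu_recording(lls_accel, lls_gyro, rate = config$rate,
                           frame_map = lls_map, calibration_window = cal_win)

  # contralateral (left) force plate at grf_rate --------------------------
  n_fp <- floor(t_end * config$grf_rate) + 1L
  t_fp <- (seq_len(n_fp) - 1) / config$grf_rate
  contra <- uniform_series(left_grf(t_fp), rate = config$grf_rate, units = "N")

  # true gait events -------------------------------------------------------
  phase_time <- function(ph) t_gait0 + (ph - phase0) * cycle_t
  right_hs <- phase_time(seq_len(config$n_strides))
  left_hs <- phase_time(seq_len(config$n_strides) + 0.5)
  left_to <- phase_time(seq_len(config$n_strides) +
                          config$double_support_fraction)
  contacts <- data.frame(
    time = sort(c(right_hs, left_hs)),
    foot = rep(c("right", "left"), config$n_strides)
  )
  contacts$position <- (seq_len(nrow(contacts)) - 1) * config$step_length

  structure(
    list(
      truth = list(
        grf = uniform_series(grf_truth, config$rate, units = "N"),
        sta = uniform_series(sta_truth, config$rate, units = "deg"),
        kam = uniform_series(kam_truth, config$rate, units = "N.m")
      ),
      l3_imu = l3_imu, lls_imu = lls_imu, contra_grf = contra,
      events = list(right_hs = right_hs, left_hs = left_hs,
                    left_to = left_to, contacts = contacts),
      config = config
    ),
    class = "synthetic_trial"
  )
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> %g steps/min, %d strides, %s GRF; %d IMU samples @ %g Hz\n",
    x$config$cadence, x$config$n_strides, x$config$grf_shape,
    n_samples(x$truth$grf), x$config$rate))
  invisible(x)
}

#' Ground-truth KAM of a synthetic trial
#'
#' Accessor returning the simulator's reference KAM waveform, so validation
#' code never recomputes the truth through the estimator under test. The
#' waveform satisfies `kam = grf * shank_length * sin(sta)` at every sample
#' by construction.
#'
#' @param trial A [simulate_trial()] result.
#' @return `uniform_series` in N.m at the IMU rate.
#' @export
ground_truth_kam <- function(trial) {
  stopifnot(inherits(trial, "synthetic_trial"))
  trial$truth$kam
}

# count local maxima of v with a minimum prominence relative to range(v)
count_local_maxima <- function(v, min_prominence = 0.01) {
  n <- length(v)
  if (n < 3L) return(0L)
  d <- diff(v)
  # candidate peaks: rising then falling (plateaus collapse to first sample)
  sign_d <- sign(d)
  nz <- sign_d != 0
  runs_idx <- which(nz)
  if (length(runs_idx) < 2L) return(0L)
  cand <- integer(0)
  prev_up <- NULL
  for (i in runs_idx) {
    if (sign_d[i] > 0) prev_up <- i
    else if (!is.null(prev_up)) { cand <- c(cand, i); prev_up <- NULL }
  }
  if (!length(cand)) return(0L)
  rng <- diff(range(v))
  if (rng == 0) return(0L)
  keep <- vapply(cand, function(i) {
    peak <- v[i]
    left_min <- min(v[1:i]); right_min <- min(v[i:n])
    (peak - max(left_min, right_min)) / rng >= min_prominence
  }, logical(1))
  sum(keep)
}
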