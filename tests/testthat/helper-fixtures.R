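# Independent brute-force CMC oracle: explicit two-level variance
# decomposition with scalar loops, kept deliberately naive and separate from
# the package's vectorized implementation.
cmc_bruteforce <- function(Y) {
  F_ <- nrow(Y); T_ <- ncol(Y)
  within_ss <- 0
  for (t in seq_len(T_)) {
    m_t <- 0
    for (f in seq_len(F_)) m_t <- m_t + Y[f, t]
    m_t <- m_t / F_
    for (f in seq_len(F_)) within_ss <- within_ss + (Y[f, t] - m_t)^2
  }
  grand <- 0
  for (f in seq_len(F_)) for (t in seq_len(T_)) grand <- grand + Y[f, t]
  grand <- grand / (F_ * T_)
  total_ss <- 0
  for (f in seq_len(F_)) for (t in seq_len(T_)) {
    total_ss <- total_ss + (Y[f, t] - grand)^2
  }
  ratio <- (within_ss / (T_ * (F_ - 1))) / (total_ss / (F_ * T_ - 1))
  if (ratio > 1) NaN else sqrt(1 - ratio)
}

# cached simulated trials so multiple tests can share one forward run
.trial_cache <- new.env(parent = emptyenv())

cached_trial <- function(cadence = 115, accel_noise_sd = 0, gyro_noise_sd = 0,
                         seed = 1, ...) {
  key <- paste(cadence, accel_noise_sd, gyro_noise_sd, seed, ...,
               sep = "|")
  if (is.null(.trial_cache[[key]])) {
    .trial_cache[[key]] <- simulate_trial(gait_sim_config(
      cadence = cadence, accel_noise_sd = accel_noise_sd,
      gyro_noise_sd = gyro_noise_sd, seed = seed, ...))
  }
  .trial_cache[[key]]
}

trial_subject <- function(trial) {
  subject_parameters(trial$config$body_mass, trial$config$shank_length,
                     initial_sta = trial$config$initial_sta)
}

passthrough_config <- function() {
  kam_config(accel_cutoff_hz = NULL, gyro_cutoff_hz = NULL,
             grf_cutoff_hz = NULL)
}

estimate_trial <- function(trial, config = kam_config()) {
  run_kam_pipeline(trial$l3_imu, trial$lls_imu, trial_subject(trial), config)
}

# early-segment CMC between estimated and ground-truth KAM for one trial
early_cmc_vs_truth <- function(trial, config = kam_config()) {
  est <- estimate_trial(trial, config)
  contra <- if (is.null(config$grf_cutoff_hz)) trial$contra_grf else
    lowpass(trial$contra_grf, config$grf_cutoff_hz, config$filter_order)
  sls <- detect_sls(contra, config$sls_threshold_n)
  a <- normalize_time(est$kam, sls, config$n_points, source = "imu")
  b <- normalize_time(ground_truth_kam(trial), sls, config$n_points,
                      source = "truth")
  cmc_segment(a, b, "early", fraction = config$split_fraction)
}
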