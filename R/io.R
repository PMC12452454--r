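#' IMU recording container
#'
#' Six synchronous channels from one sensor: a 3-axis accelerometer in g and
#' a 3-axis gyroscope in deg/s, with the sensor-to-global axis map and the
#' quiet-standing calibration window. Samples outside the sensor's
#' measurement range (accelerometer +/-16 g, gyroscope +/-1500 deg/s) are
#' accepted but flagged via the `out_of_range` attribute.
#'
#' @param accel n x 3 numeric matrix in g (or list of three
#'   [uniform_series()]).
#' @param gyro n x 3 numeric matrix in deg/s (or list of three
#'   `uniform_series`), same length as `accel`.
#' @param rate Sampling rate in Hz (200 for the sensors targeted here).
#' @param frame_map A [sensor_frame_map()].
#' @param calibration_window `c(start_s, end_s)` of the quiet-standing
#'   window, or `NULL`.
#' @param t0 Start time in s.
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(accel, gyro, rate, frame_map,
                          calibration_window = NULL, t0 = 0) {
  to_mat <- function(x, what) {
    if (is.list(x) && all(vapply(x, inherits, TRUE, "uniform_series"))) {
      x <- cbind(x[[1]]$values, x[[2]]$values, x[[3]]$values)
    }
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop("imu_recording: '", what, "' must have 3 columns")
    if (!all(is.finite(x))) stop("imu_recording: non-finite ", what, " sample")
    unname(x)
  }
  accel <- to_mat(accel, "accel")
  gyro <- to_mat(gyro, "gyro")
  if (nrow(accel) != nrow(gyro)) {
    stop("imu_recording: accel and gyro must share length (",
         nrow(accel), " vs ", nrow(gyro), ")")
  }
  stopifnot(inherits(frame_map, "sensor_frame_map"))
  out_of_range <- any(abs(accel) > 16) || any(abs(gyro) > 1500)
  if (out_of_range) {
    warning("imu_recording: samples outside sensor range ",
            "(accel +/-16 g, gyro +/-1500 deg/s); flagged")
  }
  structure(
    list(accel = accel, gyro = gyro, rate = rate, frame_map = frame_map,
         calibration_window = calibration_window, t0 = t0),
    class = "imu_recording", out_of_range = out_of_range
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s, %d samples @ %g Hz%s\n",
              x$frame_map$placement, nrow(x$accel), x$rate,
              if (is.null(x$calibration_window)) "" else
                sprintf(", calibration %.2f..%.2f s",
                        x$calibration_window[1], x$calibration_window[2])))
  invisible(x)
}

rec_times <- function(rec) rec$t0 + (seq_len(nrow(rec$accel)) - 1) / rec$rate

# --- CSV dialect ----------------------------------------------------------
# Files carry '#'-prefixed header lines ("# key: value") followed by a
# regular CSV table. Angles are degrees, accelerations g, forces newtons
# (kN declared in the header is converted).

read_hash_header <- function(path) {
  lines <- readLines(path, n = 20L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

check_uniform_time <- function(time, rate, path) {
  expected <- time[1L] + (seq_along(time) - 1) / rate
  tol <- 1e-6 / rate  # 1 ppm of the sample interval scale
  bad <- which(abs(time - expected) > pmax(tol, 1e-6 * abs(expected)))
  if (length(bad)) {
    stop("non-uniform time column in '", path, "' at row ", bad[1L],
         " (expected ", expected[bad[1L]], ", got ", time[bad[1L]], ")")
  }
}

#' Read an IMU recording from CSV
#'
#' Expects '#'-prefixed header lines declaring at least `rate_hz` (and
#' optionally `placement` and `calibration` as "start end" in seconds),
#' followed by a CSV table with columns `time, ax, ay, az, gx, gy, gz`
#' (accelerations in g, angular velocities in deg/s). The time column must
#' be uniform at the declared rate to within 1 ppm.
#'
#' @param path File path.
#' @param frame_map Optional [sensor_frame_map()]; defaults to the default
#'   map for the `placement` declared in the file.
#' @param rate Optional rate override in Hz.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, frame_map = NULL, rate = NULL) {
  if (!file.exists(path)) stop("read_imu_csv: file not found: ", path)
  kv <- read_hash_header(path)
  if (is.null(rate)) {
    if (is.null(kv$rate_hz)) stop("read_imu_csv: no 'rate_hz' header in ", path)
    rate <- as.numeric(kv$rate_hz)
  }
  if (!is.finite(rate) || rate <= 0) {
    stop("read_imu_csv: invalid sampling rate ", rate, " Hz in ", path)
  }
  d <- utils::read.csv(path, comment.char = "#")
  needed <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("read_imu_csv: missing channel '", missing[1L], "' in ", path)
  }
  check_uniform_time(d$time, rate, path)
  if (is.null(frame_map)) {
    placement <- if (!is.null(kv$placement)) kv$placement else "L3"
    frame_map <- sensor_frame_map(placement)
  }
  cal <- NULL
  if (!is.null(kv$calibration)) {
    cal <- as.numeric(strsplit(kv$calibration, "\\s+")[[1]])[1:2]
  }
  imu_recording(as.matrix(d[, c("ax", "ay", "az")]),
                as.matrix(d[, c("gx", "gy", "gz")]),
                rate = rate, frame_map = frame_map,
                calibration_window = cal, t0 = d$time[1L])
}

#' Read a force-plate vertical GRF channel from CSV
#'
#' Expects '#'-prefixed headers `rate_hz` and optionally `units` (`N`,
#' default, or `kN`, converted to N), followed by columns `time, fz`.
#'
#' @param path File path.
#' @return A `uniform_series` in N.
#' @export
read_forceplate_csv <- function(path) {
  if (!file.exists(path)) stop("read_forceplate_csv: file not found: ", path)
  kv <- read_hash_header(path)
  if (is.null(kv$rate_hz)) stop("read_forceplate_csv: no 'rate_hz' header in ", path)
  rate <- as.numeric(kv$rate_hz)
  if (!is.finite(rate) || rate <= 0) {
    stop("read_forceplate_csv: invalid sampling rate ", rate, " Hz in ", path)
  }
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "fz") %in% names(d))) {
    stop("read_forceplate_csv: need columns 'time' and 'fz' in ", path)
  }
  check_uniform_time(d$time, rate, path)
  units <- if (is.null(kv$units)) "N" else kv$units
  scale <- switch(units, N = 1, kN = 1000,
                  stop("read_forceplate_csv: unknown unit '", units, "'"))
  uniform_series(d$fz * scale, rate = rate, units = "N", t0 = d$time[1L])
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_hash_csv <- function(d, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(header), unlist(header)), con)
  cols <- vapply(d, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }, character(nrow(d)))
  if (nrow(d) == 1L) cols <- matrix(cols, 1L)
  writeLines(paste(names(d), collapse = ","), con)
  writeLines(apply(cols, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Write a synthetic trial to a directory of CSV files
#'
#' Writes `l3.csv` and `lls.csv` (IMU dialect of [read_imu_csv()]),
#' `contra_grf.csv` ([read_forceplate_csv()] dialect), `truth.csv`
#' (time, grf, sta, kam) and `config.txt` (plain key-value). Numeric values
#' are written with 17 significant digits so read-back is bit-identical.
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_trial_csv <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_imu <- function(rec, path) {
    d <- data.frame(time = rec_times(rec),
                    ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
                    gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3])
    write_hash_csv(d, path, list(
      rate_hz = fmt_num(rec$rate), placement = rec$frame_map$placement,
      calibration = paste(fmt_num(rec$calibration_window), collapse = " "),
      units_accel = "g", units_gyro = "deg/s"))
  }
  write_imu(trial$l3_imu, file.path(dir, "l3.csv"))
  write_imu(trial$lls_imu, file.path(dir, "lls.csv"))
  write_hash_csv(
    data.frame(time = series_times(trial$contra_grf),
               fz = trial$contra_grf$values),
    file.path(dir, "contra_grf.csv"),
    list(rate_hz = fmt_num(trial$contra_grf$rate), units = "N"))
  write_hash_csv(
    data.frame(time = series_times(trial$truth$grf),
               grf = trial$truth$grf$values,
               sta = trial$truth$sta$values,
               kam = trial$truth$kam$values),
    file.path(dir, "truth.csv"),
    list(rate_hz = fmt_num(trial$config$rate),
         units = "N; deg; N.m"))
  cfg <- trial$config
  write_run_config(cfg[!vapply(cfg, is.null, TRUE)],
                   file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write / read a plain key-value configuration file
#'
#' One `key: value` pair per line; numbers are parsed back as numerics,
#' everything else as strings. Used by the command-line interface so every
#' run's resolved configuration is auditable.
#'
#' @param config Named list of scalar values.
#' @param path File path.
#' @return `write_run_config`: the path, invisibly. `read_run_config`: a
#'   named list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) paste(fmt_num(v), collapse = " ") else
      paste(as.character(v), collapse = " ")
  }, character(1))
  writeLines(sprintf("%s: %s", names(config), vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("read_run_config: cannot parse line: ", ln)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
    out[[m[2]]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Write a similarity report
#'
#' Writes the per-trial / per-segment CMC results as a machine-readable CSV
#' (NaN rendered literally as `"NaN"`) plus a short human-readable summary
#' with category labels.
#'
#' @param results Data frame from [cmc_table()] (columns `condition`,
#'   `trial`, `segment`, `cmc`, `category`); at least one row.
#' @param path Output CSV path; the summary is written alongside with
#'   extension `.txt`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("write_report: 'results' must be a data frame with at least one row")
  }
  needed <- c("condition", "trial", "segment", "cmc", "category")
  missing <- setdiff(needed, names(results))
  if (length(missing)) {
    stop("write_report: missing column '", missing[1L], "'")
  }
  out <- results
  # render NaN literally (write.csv would fold it into the NA marker)
  out$cmc <- ifelse(is.nan(out$cmc), "NaN", fmt_num(out$cmc))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c("Waveform similarity report (CMC)", "")
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    lines <- c(lines, sprintf(
      "condition %-10s trial %-3s %-6s CMC %-7s %s",
      r$condition, as.character(r$trial), r$segment,
      if (is.nan(r$cmc)) "NaN" else sprintf("%.3f", r$cmc), r$category))
  }
  writeLines(lines, txt)
  invisible(c(csv = path, summary = txt))
}

#' Published reference CMC values for the two-IMU KAM method
#'
#' Reads the per-trial CMC benchmark table shipped with the package: CMC
#' between IMU-estimated and optically measured KAM waveforms for three
#' healthy participants walking at three metronome-controlled cadences
#' (preferred 115, reduced 100, lowest 85 steps/min), two trials each,
#' scored separately over the early and late halves of single-limb support.
#' `NaN` entries mark trials where the CMC radicand was negative (complex
#' result). Use [summarize_cmc_table()] to reproduce the reported
#' per-condition ranges.
#'
#' @param what `"kam"` (default): the KAM comparison table.
#' @return Data frame with columns `participant`, `trial`, `condition`,
#'   `segment`, `cmc`.
#' @export
read_reference_cmc <- function(what = "kam") {
  path <- system.file("extdata", paste0("reference_cmc_", what, ".csv"),
                      package = "imukam", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$cmc <- as.numeric(d$cmc)  # "NaN" strings parse to NaN
  d
}
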