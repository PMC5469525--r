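#' Construct an IMU recording object
#'
#' Bundles synchronized accelerometer/gyroscope streams from the three
#' sensor placements (waist, left thigh, right thigh) together with the
#' metadata the pipeline needs: sampling rate, the static standing window
#' used for orientation initialization, per-sensor calibration offsets and
#' the declared forward (anterior) axis of each sensor.
#'
#' @param sensors named list with elements `waist`, `thigh_left`,
#'   `thigh_right`; each a list with `acc` and `gyro` (n x 3 matrices,
#'   m/s^2 and rad/s, sensor frame) and `forward_axis` (unit 3-vector in
#'   the sensor frame).
#' @param sample_rate sampling frequency in Hz.
#' @param static_window integer `c(start, end)`, 1-based inclusive sample
#'   range of the pre-walk quiet standing phase (at least 2 s).
#' @param offsets optional named list of per-sensor lists with `acc` and
#'   `gyro` additive offsets (length-3 each); defaults to zero.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(sensors, sample_rate = 100,
                          static_window, offsets = NULL) {
  required <- c("waist", "thigh_left", "thigh_right")
  missing <- setdiff(required, names(sensors))
  if (length(missing) > 0)
    stop("placement ", missing[1L], " absent")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  n <- nrow(sensors[[1L]]$acc)
  for (p in required) {
    s <- sensors[[p]]
    if (!is.matrix(s$acc) || ncol(s$acc) != 3L ||
        !is.matrix(s$gyro) || ncol(s$gyro) != 3L)
      stop("sensor ", p, " must carry n x 3 acc and gyro matrices")
    if (nrow(s$acc) != n || nrow(s$gyro) != n)
      stop("sensor streams have unequal lengths")
    if (is.null(s$forward_axis)) sensors[[p]]$forward_axis <- c(1, 0, 0)
  }
  static_window <- as.integer(round(static_window))
  if (length(static_window) != 2L || static_window[1L] < 1L ||
      static_window[2L] > n || diff(static_window) + 1L < 2 * sample_rate)
    stop("static_window must span at least 2 s inside the recording")
  if (is.null(offsets))
    offsets <- stats::setNames(rep(list(list(acc = c(0, 0, 0),
                                             gyro = c(0, 0, 0))),
                                   3L), required)
  for (p in required) {
    o <- offsets[[p]]
    if (!all(is.finite(c(o$acc, o$gyro))))
      stop("offsets must be finite")
  }
  structure(list(sample_rate = sample_rate, sensors = sensors[required],
                 static_window = static_window, offsets = offsets),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- nrow(x$sensors$waist$acc)
  cat(sprintf(
    "IMU recording: %d samples (%.1f s at %g Hz), 3 sensors\n",
    n, n / x$sample_rate, x$sample_rate))
  cat(sprintf("  static window: samples %d-%d (%.1f s)\n",
              x$static_window[1L], x$static_window[2L],
              diff(x$static_window) / x$sample_rate))
  invisible(x)
}

sensor_cols <- function(placement) {
  paste0(placement, "_", c("ax", "ay", "az", "gx", "gy", "gz"))
}

#' Read an IMU recording from CSV plus JSON sidecar
#'
#' The CSV holds one timestamp column `t` (seconds) followed by six columns
#' per placement, named `<placement>_{ax,ay,az,gx,gy,gz}`. The sidecar JSON
#' names the sample rate, the acceleration unit (`"g"` or `"m/s2"`; data
#' are converted to m/s^2 internally with g = 9.81), the static window, the
#' per-sensor forward axes and the calibration offsets.
#'
#' @param path CSV file path.
#' @param metadata_path JSON sidecar path.
#' @return an [imu_recording()] object.
#' @export
load_recording <- function(path, metadata_path) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  dat <- utils::read.csv(path, check.names = FALSE)
  fs <- meta$sample_rate
  if (is.null(fs) || fs <= 0) stop("sidecar must give a positive sample_rate")
  if (!"t" %in% names(dat)) stop("CSV must contain a timestamp column 't'")
  dt <- diff(dat$t)
  if (length(dt) > 0 && (max(dt) - min(dt)) > 0.01 * stats::median(dt))
    stop("non-uniform timestamps: jitter exceeds 1% of the sample interval")
  unit <- if (is.null(meta$unit)) "m/s2" else meta$unit
  acc_scale <- if (identical(unit, "g")) GRAVITY else 1
  sensors <- list()
  for (p in c("waist", "thigh_left", "thigh_right")) {
    cols <- sensor_cols(p)
    if (!all(cols %in% names(dat)))
      stop("placement ", p, " absent")
    m <- as.matrix(dat[, cols])
    fwd <- meta$placements[[p]]$forward_axis
    if (is.null(fwd)) fwd <- c(1, 0, 0)
    sensors[[p]] <- list(acc = unname(m[, 1:3, drop = FALSE]) * acc_scale,
                         gyro = unname(m[, 4:6, drop = FALSE]),
                         forward_axis = as.numeric(fwd))
  }
  offsets <- NULL
  if (!is.null(meta$offsets)) {
    offsets <- lapply(meta$offsets, function(o)
      list(acc = as.numeric(o$acc) * acc_scale, gyro = as.numeric(o$gyro)))
  }
  imu_recording(sensors, sample_rate = fs,
                static_window = as.numeric(meta$static_window),
                offsets = offsets)
}

#' Write an IMU recording to CSV plus JSON sidecar
#'
#' Inverse of [load_recording()]; always writes accelerations in m/s^2.
#'
#' @param rec an [imu_recording()] object.
#' @param path output CSV path.
#' @param metadata_path output JSON path.
#' @return invisibly, `path`.
#' @export
write_recording <- function(rec, path, metadata_path) {
  n <- nrow(rec$sensors$waist$acc)
  out <- data.frame(t = (seq_len(n) - 1L) / rec$sample_rate)
  for (p in names(rec$sensors)) {
    block <- cbind(rec$sensors[[p]]$acc, rec$sensors[[p]]$gyro)
    colnames(block) <- sensor_cols(p)
    out <- cbind(out, block)
  }
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(
    sample_rate = rec$sample_rate, unit = "m/s2",
    placements = lapply(rec$sensors, function(s)
      list(forward_axis = s$forward_axis)),
    static_window = rec$static_window,
    offsets = rec$offsets)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Apply additive calibration offsets
#'
#' Shifts every accelerometer and gyroscope channel by its per-sensor,
#' per-axis offset established during bench calibration, converting
#' measured values to actual acceleration and angular velocity.
#'
#' @param rec an [imu_recording()] object.
#' @param offsets named list (by placement) of lists with `acc` and `gyro`
#'   length-3 numeric offsets; defaults to the offsets stored in `rec`.
#' @return the corrected `imu_recording`.
#' @export
apply_offsets <- function(rec, offsets = rec$offsets) {
  for (p in names(rec$sensors)) {
    o <- offsets[[p]]
    if (is.null(o)) next
    if (!all(is.finite(c(o$acc, o$gyro)))) stop("offsets must be finite")
    rec$sensors[[p]]$acc <-
      sweep(rec$sensors[[p]]$acc, 2L, as.numeric(o$acc), "+")
    rec$sensors[[p]]$gyro <-
      sweep(rec$sensors[[p]]$gyro, 2L, as.numeric(o$gyro), "+")
  }
  rec$offsets <- stats::setNames(rep(list(list(acc = c(0, 0, 0),
                                               gyro = c(0, 0, 0))),
                                     length(rec$sensors)),
                                 names(rec$sensors))
  rec
}
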