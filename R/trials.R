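#' sEMG trial container
#'
#' A three-channel surface-EMG recording from the anterior, middle and
#' posterior deltoid, on a shared clock with the IMU stream of the same trial.
#' Amplitudes are in arbitrary units (the acquisition chain's ADC scale is not
#' part of the data model); the loader rejects non-finite samples.
#'
#' @param subject_id,trial_id Identifier strings.
#' @param fs_emg Sampling rate in Hz (nominally 10000).
#' @param samples Numeric matrix `[n_samples x 3]`, one column per muscle.
#' @param channels Character vector of three muscle labels.
#' @param t0 Clock origin of the first sample, seconds on the shared clock.
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(subject_id, trial_id, fs_emg, samples,
                      channels = c("anterior_deltoid", "middle_deltoid",
                                   "posterior_deltoid"),
                      t0 = 0) {
  if (!is.numeric(fs_emg) || length(fs_emg) != 1L || fs_emg <= 0)
    stopf("fs_emg must be a positive scalar")
  check_numeric_matrix(samples, "sEMG samples")
  if (ncol(samples) != 3L)
    stopf("sEMG trial must have exactly 3 channels, got %d", ncol(samples))
  if (length(channels) != 3L) stopf("exactly 3 channel labels required")
  colnames(samples) <- channels
  structure(list(subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id),
                 fs_emg = as.numeric(fs_emg), channels = channels,
                 samples = samples, t0 = as.numeric(t0)),
            class = "emg_trial")
}

#' IMU trial container
#'
#' Triaxial accelerometer and gyroscope streams (optionally device-reported
#' Euler angles) from an arm-mounted MPU6050-class sensor, X axis anterior.
#' Canonical units: acceleration in g, angular velocity in deg/s, angles deg.
#'
#' @param subject_id,trial_id Identifier strings.
#' @param fs_imu Sampling rate in Hz (nominally 100).
#' @param acc `[n x 3]` acceleration, g.
#' @param gyro `[n x 3]` angular velocity, deg/s.
#' @param euler_device Optional `[n x 3]` device Euler angles (pitch, roll,
#'   yaw), degrees.
#' @param t0 Clock origin, seconds on the shared clock.
#' @return An object of class `imu_trial`.
#' @export
imu_trial <- function(subject_id, trial_id, fs_imu, acc, gyro,
                      euler_device = NULL, t0 = 0) {
  if (!is.numeric(fs_imu) || length(fs_imu) != 1L || fs_imu <= 0)
    stopf("fs_imu must be a positive scalar")
  check_numeric_matrix(acc, "acc")
  check_numeric_matrix(gyro, "gyro")
  if (ncol(acc) != 3L || ncol(gyro) != 3L)
    stopf("acc and gyro must each have 3 columns")
  if (nrow(acc) != nrow(gyro))
    stopf("acc and gyro must have the same number of samples")
  if (!is.null(euler_device)) {
    check_numeric_matrix(euler_device, "euler_device")
    if (nrow(euler_device) != nrow(acc) || ncol(euler_device) != 3L)
      stopf("euler_device must be [n x 3] matching acc")
  }
  colnames(acc) <- c("acc_x", "acc_y", "acc_z")
  colnames(gyro) <- c("gyro_x", "gyro_y", "gyro_z")
  structure(list(subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id),
                 fs_imu = as.numeric(fs_imu), acc = acc, gyro = gyro,
                 euler_device = euler_device, t0 = as.numeric(t0)),
            class = "imu_trial")
}

#' A labelled trial: sEMG + IMU + MMT grade
#'
#' @param emg An [emg_trial()].
#' @param imu An [imu_trial()] for the same subject/trial.
#' @param grade Muscle-strength label on the MMT scale, in `[2, 5]`.
#' @param usable Logical; `FALSE` marks trials excluded for fatigue/QC.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(emg, imu, grade, usable = TRUE) {
  stopifnot(inherits(emg, "emg_trial"), inherits(imu, "imu_trial"))
  if (emg$subject_id != imu$subject_id || emg$trial_id != imu$trial_id)
    stopf("emg and imu streams disagree on subject/trial id")
  if (!is.numeric(grade) || length(grade) != 1L || grade < 2 || grade > 5)
    stopf("grade must lie in [2, 5] (MMT grades examined), got %s",
          format(grade))
  structure(list(emg = emg, imu = imu, grade = as.numeric(grade),
                 usable = isTRUE(usable)),
            class = "trial_record")
}

emg_span <- function(emg) c(emg$t0, emg$t0 + (nrow(emg$samples) - 1) / emg$fs_emg)
imu_span <- function(imu) c(imu$t0, imu$t0 + (nrow(imu$acc) - 1) / imu$fs_imu)

#' Temporally align the sEMG and IMU streams of a trial
#'
#' Intersects the time spans of the two streams on the shared clock and trims
#' each stream to the overlap window. No resampling is done; features are
#' computed per stream at its own rate. An overlap shorter than
#' `min_overlap` seconds (one flexion repetition takes seconds, so a shorter
#' overlap indicates a clock fault) is rejected.
#'
#' @param emg An [emg_trial()].
#' @param imu An [imu_trial()].
#' @param min_overlap Minimum usable overlap, seconds (default 0.5).
#' @return An object of class `aligned_trial` with fields `emg`, `imu`
#'   (trimmed) and `overlap_window` (`c(t_start, t_end)`).
#' @export
align_streams <- function(emg, imu, min_overlap = 0.5) {
  stopifnot(inherits(emg, "emg_trial"), inherits(imu, "imu_trial"))
  se <- emg_span(emg); si <- imu_span(imu)
  t_start <- max(se[1], si[1]); t_end <- min(se[2], si[2])
  if (t_end - t_start < min_overlap)
    stopf("stream overlap %.3f s below the %.2f s minimum (clock fault?)",
          max(0, t_end - t_start), min_overlap)
  trim <- function(t0, fs, n) {
    idx <- which(t0 + (0:(n - 1)) / fs >= t_start - 1e-12 &
                 t0 + (0:(n - 1)) / fs <= t_end + 1e-12)
    idx
  }
  ie <- trim(emg$t0, emg$fs_emg, nrow(emg$samples))
  ii <- trim(imu$t0, imu$fs_imu, nrow(imu$acc))
  emg2 <- emg
  emg2$samples <- emg$samples[ie, , drop = FALSE]
  emg2$t0 <- emg$t0 + (ie[1] - 1) / emg$fs_emg
  imu2 <- imu
  imu2$acc <- imu$acc[ii, , drop = FALSE]
  imu2$gyro <- imu$gyro[ii, , drop = FALSE]
  if (!is.null(imu$euler_device))
    imu2$euler_device <- imu$euler_device[ii, , drop = FALSE]
  imu2$t0 <- imu$t0 + (ii[1] - 1) / imu$fs_imu
  structure(list(emg = emg2, imu = imu2,
                 overlap_window = c(t_start, t_end)),
            class = "aligned_trial")
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("<emg_trial> %s/%s: %d samples x 3 ch @ %g Hz (%.2f s from t0=%.2f)\n",
              x$subject_id, x$trial_id, nrow(x$samples), x$fs_emg,
              nrow(x$samples) / x$fs_emg, x$t0))
  invisible(x)
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> %s/%s: %d samples @ %g Hz, acc[g] gyro[deg/s]%s\n",
              x$subject_id, x$trial_id, nrow(x$acc), x$fs_imu,
              if (is.null(x$euler_device)) "" else " + device Euler"))
  invisible(x)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s/%s grade %g%s\n", x$emg$subject_id,
              x$emg$trial_id, x$grade, if (x$usable) "" else " (unusable)"))
  invisible(x)
}
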