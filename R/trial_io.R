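# On-disk trial layout: one directory per trial holding
#   emg.csv  - t, <three muscle columns>
#   imu.csv  - t, acc_x..acc_z, gyro_x..gyro_z[, pitch, roll, yaw]
#   meta.yaml- subject_id, trial_id, grade, fs_emg, fs_imu, acc_units,
#              gyro_units, usable
# Plain text chosen for inspectability. Numbers are written with 17
# significant digits so write/read round-trips bit-identically.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a trial to a directory
#'
#' Serializes a [trial_record()] as the documented plain-text layout
#' (`emg.csv`, `imu.csv`, `meta.yaml`). Canonical units are assumed:
#' acceleration in g, angular velocity in deg/s, angles in degrees.
#'
#' @param record A [trial_record()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_trial()]
#' @export
write_trial <- function(record, path) {
  stopifnot(inherits(record, "trial_record"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  emg <- record$emg; imu <- record$imu
  te <- emg$t0 + (seq_len(nrow(emg$samples)) - 1) / emg$fs_emg
  edf <- data.frame(t = te, emg$samples, check.names = FALSE)
  write_num_csv(edf, file.path(path, "emg.csv"))
  ti <- imu$t0 + (seq_len(nrow(imu$acc)) - 1) / imu$fs_imu
  idf <- data.frame(t = ti, imu$acc, imu$gyro, check.names = FALSE)
  if (!is.null(imu$euler_device)) {
    ed <- imu$euler_device
    colnames(ed) <- c("pitch", "roll", "yaw")
    idf <- cbind(idf, ed)
  }
  write_num_csv(idf, file.path(path, "imu.csv"))
  meta <- list(subject_id = emg$subject_id, trial_id = emg$trial_id,
               grade = record$grade, usable = record$usable,
               fs_emg = emg$fs_emg, fs_imu = imu$fs_imu,
               acc_units = "g", gyro_units = "deg/s",
               channels = as.list(emg$channels))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a trial from a directory
#'
#' Loads and validates one trial written in the documented layout. Units are
#' converted to canonical on load: acceleration declared in `m/s2` is divided
#' by 9.80665, angular velocity in `rad/s` is converted to deg/s.
#'
#' @param path Trial directory containing `emg.csv`, `imu.csv`, `meta.yaml`.
#' @return A validated [trial_record()].
#' @export
read_trial <- function(path) {
  need <- file.path(path, c("emg.csv", "imu.csv", "meta.yaml"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stopf("trial directory %s is missing: %s", path,
          paste(basename(miss), collapse = ", "))
  meta <- yaml::read_yaml(need[3])
  for (k in c("subject_id", "trial_id", "grade", "fs_emg", "fs_imu"))
    if (is.null(meta[[k]])) stopf("meta.yaml missing field '%s'", k)
  if (!is.numeric(meta$grade) || meta$grade < 2 || meta$grade > 5)
    stopf("label error: grade %s outside [2, 5]", format(meta$grade))

  edf <- utils::read.csv(need[1], check.names = FALSE)
  channels <- if (!is.null(meta$channels)) unlist(meta$channels) else
    c("anterior_deltoid", "middle_deltoid", "posterior_deltoid")
  if (!all(channels %in% names(edf)))
    stopf("format error: emg.csv lacks channel(s) %s",
          paste(setdiff(channels, names(edf)), collapse = ", "))
  if (length(intersect(channels, names(edf))) < 3L)
    stopf("format error: sEMG requires 3 channels")
  es <- as.matrix(edf[, channels, drop = FALSE])
  if (anyNA(es) || !is.numeric(es))
    stopf("data error: non-numeric or NA sEMG sample in %s", path)

  idf <- utils::read.csv(need[2], check.names = FALSE)
  acc_cols <- c("acc_x", "acc_y", "acc_z")
  gyro_cols <- c("gyro_x", "gyro_y", "gyro_z")
  if (!all(c(acc_cols, gyro_cols) %in% names(idf)))
    stopf("format error: imu.csv must carry %s",
          paste(c(acc_cols, gyro_cols), collapse = ", "))
  acc <- as.matrix(idf[, acc_cols]); gyro <- as.matrix(idf[, gyro_cols])
  if (anyNA(acc) || anyNA(gyro))
    stopf("data error: NA IMU sample in %s", path)
  acc_units <- if (is.null(meta$acc_units)) "g" else meta$acc_units
  if (acc_units %in% c("m/s2", "m/s^2", "ms2")) acc <- acc / 9.80665
  else if (acc_units != "g") stopf("unknown acc_units '%s'", acc_units)
  gyro_units <- if (is.null(meta$gyro_units)) "deg/s" else meta$gyro_units
  if (gyro_units == "rad/s") gyro <- gyro * 180 / pi
  else if (gyro_units != "deg/s") stopf("unknown gyro_units '%s'", gyro_units)
  euler <- NULL
  if (all(c("pitch", "roll", "yaw") %in% names(idf)))
    euler <- as.matrix(idf[, c("pitch", "roll", "yaw")])

  emg <- emg_trial(meta$subject_id, meta$trial_id, meta$fs_emg, es,
                   channels = channels, t0 = edf$t[1])
  imu <- imu_trial(meta$subject_id, meta$trial_id, meta$fs_imu, acc, gyro,
                   euler_device = euler, t0 = idf$t[1])
  trial_record(emg, imu, meta$grade,
               usable = if (is.null(meta$usable)) TRUE else isTRUE(meta$usable))
}
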