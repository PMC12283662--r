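#' Accelerometer inclination angles
#'
#' Projects the (quasi-static) gravity vector measured by the accelerometer
#' onto roll and pitch: `roll = atan2(a_y, a_z)`,
#' `pitch = atan2(-a_x, sqrt(a_y^2 + a_z^2))`, in degrees. With the sensor's
#' X axis anterior these are the tilt angles about the sensor X and Y axes;
#' yaw is unobservable from gravity alone.
#'
#' @param acc `[n x 3]` acceleration matrix, any consistent units.
#' @return List with numeric vectors `roll` and `pitch` (degrees).
#' @export
accel_angles <- function(acc) {
  check_numeric_matrix(acc, "acc")
  if (ncol(acc) != 3L) stopf("acc must have 3 columns")
  norms <- sqrt(rowSums(acc^2))
  if (any(norms <= 0))
    stopf("zero acceleration vector at sample %d: inclination undefined",
          which(norms <= 0)[1L])
  list(roll = atan2(acc[, 2], acc[, 3]) * 180 / pi,
       pitch = atan2(-acc[, 1], sqrt(acc[, 2]^2 + acc[, 3]^2)) * 180 / pi)
}

#' First-order complementary filter
#'
#' Fuses gyroscope rates with accelerometer inclination per step:
#' \deqn{roll_t = K (roll_{t-1} + \omega_x \Delta t) + (1-K)\, roll^{acc}_t}
#' \deqn{pitch_t = K (pitch_{t-1} + \omega_y \Delta t) + (1-K)\, pitch^{acc}_t}
#' \deqn{yaw_t = yaw_{t-1} + \omega_z \Delta t}
#' The gyro term is the previous fused estimate propagated by the current
#' rate (an independent pure-gyro integrator drifts unboundedly and defeats
#' the fusion); yaw has no gravity reference and is integrated only. `K`
#' balances short-term gyro responsiveness against long-term accelerometer
#' stability; 0.4 worked well empirically for shoulder-flexion tracking.
#'
#' @param gyro `[n x 3]` angular velocity, deg/s (columns x, y, z).
#' @param roll_acc,pitch_acc Accelerometer angle series, degrees
#'   (see [accel_angles()]).
#' @param K Fusion coefficient in `[0, 1]` (default 0.4). `K = 0` returns the
#'   accelerometer angles; `K = 1` is pure gyro integration.
#' @param dt Sample interval in seconds (1/fs_imu).
#' @param initial_angles Initial `c(roll, pitch, yaw)` in degrees.
#' @return An object of class `orientation_series`: list of numeric vectors
#'   `roll`, `pitch`, `yaw` (degrees, same length as the input).
#' @export
complementary_filter <- function(gyro, roll_acc, pitch_acc, K = 0.4, dt,
                                 initial_angles = c(0, 0, 0)) {
  check_numeric_matrix(gyro, "gyro")
  n <- nrow(gyro)
  if (length(roll_acc) != n || length(pitch_acc) != n)
    stopf("gyro and accelerometer angle series must have equal length")
  if (!is.numeric(K) || K < 0 || K > 1) stopf("K must lie in [0, 1]")
  if (!is.numeric(dt) || dt <= 0) stopf("dt must be positive")
  roll <- pitch <- yaw <- numeric(n)
  r <- initial_angles[1]; p <- initial_angles[2]; y <- initial_angles[3]
  for (i in seq_len(n)) {
    r <- K * (r + gyro[i, 1] * dt) + (1 - K) * roll_acc[i]
    p <- K * (p + gyro[i, 2] * dt) + (1 - K) * pitch_acc[i]
    y <- y + gyro[i, 3] * dt
    roll[i] <- r; pitch[i] <- p; yaw[i] <- y
  }
  structure(list(roll = roll, pitch = pitch, yaw = yaw),
            class = "orientation_series")
}

#' Fuse an IMU trial into an orientation series
#'
#' Convenience wrapper: accelerometer inclination via [accel_angles()] fused
#' by [complementary_filter()] at the trial's sampling interval. When
#' `use_device_angles = TRUE` and the trial carries device-reported Euler
#' angles, those are returned verbatim instead (the sensor computes
#' orientation onboard); the default re-fuses from raw streams for
#' reproducibility.
#'
#' @param imu An [imu_trial()].
#' @param K Fusion coefficient (default 0.4).
#' @param use_device_angles Use `euler_device` if present (default `FALSE`).
#' @param initial_angles Initial `c(roll, pitch, yaw)`, degrees.
#' @return An `orientation_series`.
#' @export
fuse_orientation <- function(imu, K = 0.4, use_device_angles = FALSE,
                             initial_angles = c(0, 0, 0)) {
  stopifnot(inherits(imu, "imu_trial"))
  if (use_device_angles && !is.null(imu$euler_device)) {
    ed <- imu$euler_device
    return(structure(list(roll = ed[, 2], pitch = ed[, 1], yaw = ed[, 3]),
                     class = "orientation_series"))
  }
  aa <- accel_angles(imu$acc)
  complementary_filter(imu$gyro, aa$roll, aa$pitch, K = K, dt = 1 / imu$fs_imu,
                       initial_angles = initial_angles)
}

#' Per-trial IMU scalar features
#'
#' Reduces the nine IMU channels to one scalar each: the peak absolute value
#' over the trial for acceleration and angular velocity, and the peak
#' absolute excursion from the trial's initial angle for the Euler angles
#' (muscle strength relates to peak kinematics). `rule` switches to mean or
#' range reduction.
#'
#' @param imu An [imu_trial()].
#' @param orient An `orientation_series` for the trial (see
#'   [fuse_orientation()]).
#' @param rule Reduction rule: `"peak"` (default), `"mean"` or `"range"`.
#' @return Named numeric vector of length 9:
#'   `acc_x/y/z`, `gyro_x/y/z`, `pitch`, `roll`, `yaw`.
#' @export
imu_scalarize <- function(imu, orient, rule = c("peak", "mean", "range")) {
  stopifnot(inherits(imu, "imu_trial"),
            inherits(orient, "orientation_series"))
  rule <- match.arg(rule)
  red <- switch(rule,
                peak = function(v) max(abs(v)),
                mean = function(v) mean(v),
                range = function(v) diff(range(v)))
  ang <- function(v) red(v - v[1L])
  c(acc_x = red(imu$acc[, 1]), acc_y = red(imu$acc[, 2]),
    acc_z = red(imu$acc[, 3]),
    gyro_x = red(imu$gyro[, 1]), gyro_y = red(imu$gyro[, 2]),
    gyro_z = red(imu$gyro[, 3]),
    pitch = ang(orient$pitch), roll = ang(orient$roll),
    yaw = ang(orient$yaw))
}
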