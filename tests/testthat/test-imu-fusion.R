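test_that("accelerometer angles invert the gravity-projection model", {
  aa <- accel_angles(rbind(c(0, 0, 1), c(0, 1, 0),
                           c(-sin(pi / 6), 0, cos(pi / 6))))
  expect_equal(aa$roll, c(0, 90, 0), tolerance = 1e-12)
  expect_equal(aa$pitch, c(0, 0, 30), tolerance = 1e-12)
  expect_error(accel_angles(rbind(c(0, 0, 1), c(0, 0, 0))), "zero")
})

test_that("filter limits reduce to pure accelerometer / pure gyro", {
  n <- 200
  set.seed(8)
  roll_acc <- rnorm(n, 10, 5); pitch_acc <- rnorm(n, -5, 5)
  gyro <- matrix(rnorm(3 * n), n, 3)
  o0 <- complementary_filter(gyro, roll_acc, pitch_acc, K = 0, dt = 0.01)
  expect_equal(o0$roll, roll_acc, tolerance = 1e-12)
  expect_equal(o0$pitch, pitch_acc, tolerance = 1e-12)

  gz <- gyro; gz[, 1] <- 0
  o1 <- complementary_filter(gz, roll_acc, pitch_acc, K = 1, dt = 0.01)
  expect_equal(o1$roll, rep(0, n))  # nothing to integrate, accel ignored
})

test_that("yaw is the exact rectangular integral of the z rate", {
  n <- 200
  o <- complementary_filter(cbind(0, 0, rep(10, n)), numeric(n), numeric(n),
                            K = 0.4, dt = 0.01)
  expect_equal(o$yaw[n], 20, tolerance = 1e-9)

  set.seed(3)
  wz <- rep(rnorm(10), each = 25)  # piecewise-constant rate
  o2 <- complementary_filter(cbind(0, 0, wz), numeric(250), numeric(250),
                             K = 0.4, dt = 0.02)
  expect_equal(o2$yaw, cumsum(wz) * 0.02, tolerance = 1e-9)

  # superposition: yaw is linear in the z rate
  wa <- rnorm(250); wb <- rnorm(250)
  ya <- complementary_filter(cbind(0, 0, wa), numeric(250), numeric(250),
                             K = 0.4, dt = 0.02)$yaw
  yb <- complementary_filter(cbind(0, 0, wb), numeric(250), numeric(250),
                             K = 0.4, dt = 0.02)$yaw
  yab <- complementary_filter(cbind(0, 0, wa + wb), numeric(250),
                              numeric(250), K = 0.4, dt = 0.02)$yaw
  expect_equal(yab, ya + yb, tolerance = 1e-9)
})

test_that("a constant accelerometer angle is approached geometrically", {
  n <- 60; theta <- 25; K <- 0.6
  o <- complementary_filter(matrix(0, n, 3), rep(theta, n), rep(theta, n),
                            K = K, dt = 0.01)
  # affine recursion r <- K r + (1-K) theta from 0: error decays as K^t
  expect_equal(o$roll, theta * (1 - K^(1:n)), tolerance = 1e-10)
})

test_that("mismatched series lengths and bad K are rejected", {
  expect_error(complementary_filter(matrix(0, 10, 3), numeric(9),
                                    numeric(10), K = 0.4, dt = 0.01),
               "length")
  expect_error(complementary_filter(matrix(0, 10, 3), numeric(10),
                                    numeric(10), K = 1.2, dt = 0.01),
               "K")
})

test_that("noiseless generated trials are tracked within 2 degrees", {
  cfg <- sim_config(n_subjects = 1L, trials_per_subject = 1L,
                    fs_emg = 1000, acc_noise_sd = 0, gyro_noise_sd = 0,
                    yaw_amp = 0)
  rec <- simulate_trial(4, cfg, seed = 2)
  aa <- accel_angles(rec$imu$acc)
  n <- nrow(rec$imu$acc)
  true_pitch <- strengthsense:::flexion_trajectory(
    (0:(n - 1)) / cfg$fs_imu, cfg$trial_duration, cfg$angle_peak[3])$theta
  expect_equal(aa$pitch, true_pitch, tolerance = 1e-9)

  o <- fuse_orientation(rec$imu, K = 0.4)
  after <- 51:n  # past the initial transient
  expect_lt(max(abs(o$pitch[after] - true_pitch[after])), 2)
})

test_that("scalarization reduces channels to peak excursions", {
  imu <- imu_trial("S", "T", 100,
                   acc = cbind(0, 0, rep(1, 3)),
                   gyro = cbind(c(1, -5, 3), 0, 0))
  orient <- structure(list(roll = c(0, 0, 0),
                           pitch = c(10, 55, 100),
                           yaw = c(5, 5, 5)),
                      class = "orientation_series")
  f <- imu_scalarize(imu, orient)
  expect_equal(unname(f[c("gyro_x", "acc_z", "pitch", "yaw", "roll")]),
               c(5, 1, 90, 0, 0))
  expect_length(f, 9)
})
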