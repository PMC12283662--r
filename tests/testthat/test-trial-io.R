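test_that("write/read round-trips a trial bit-identically", {
  rec <- make_record(grade = 4, seed = 11, n = 500)
  dir <- withr::local_tempdir()
  write_trial(rec, dir)
  back <- read_trial(dir)
  expect_identical(back$emg$samples, rec$emg$samples)
  expect_identical(back$imu$acc, rec$imu$acc)
  expect_identical(back$imu$gyro, rec$imu$gyro)
  expect_identical(back$grade, rec$grade)
  expect_identical(back$emg$fs_emg, rec$emg$fs_emg)
  expect_identical(back$emg$t0, rec$emg$t0)
})

test_that("loader validates structure, labels and units", {
  rec <- make_record(seed = 2, n = 200)
  dir <- withr::local_tempdir()
  write_trial(rec, dir)

  # drop a channel column -> format error
  edf <- read.csv(file.path(dir, "emg.csv"), check.names = FALSE)
  write.csv(edf[, 1:3], file.path(dir, "emg.csv"), row.names = FALSE)
  expect_error(read_trial(dir), "format error")
  write_trial(rec, dir)

  # corrupt a sample -> data error
  edf <- read.csv(file.path(dir, "emg.csv"), check.names = FALSE)
  edf[5, 2] <- NA
  write.csv(edf, file.path(dir, "emg.csv"), row.names = FALSE)
  expect_error(read_trial(dir), "data error")
  write_trial(rec, dir)

  # grade outside the examined MMT range -> label error
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  meta$grade <- 1
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  expect_error(read_trial(dir), "label error")

  # m/s^2 acceleration converts to g on load
  meta$grade <- 3
  meta$acc_units <- "m/s2"
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  back <- read_trial(dir)
  expect_equal(back$imu$acc, rec$imu$acc / 9.80665)
})

test_that("constructors enforce the channel and grade invariants", {
  expect_error(emg_trial("S", "T", 2000, matrix(0, 100, 2)), "3 channels")
  expect_error(trial_record(make_emg(n = 100), make_imu(n = 10), 1.5),
               "grade")
  expect_error(emg_trial("S", "T", 2000, matrix(c(NA, rnorm(299)), 100, 3)),
               "NA")
})

test_that("generator output round-trips through the loader contract", {
  cfg <- sim_config(n_subjects = 1L, trials_per_subject = 1L,
                    fs_emg = 10000, trial_duration = 1)
  rec <- simulate_trial(3, cfg, seed = 1)
  dir <- withr::local_tempdir()
  write_trial(rec, dir)
  back <- read_trial(dir)
  expect_equal(back$emg$fs_emg, 10000)
  expect_equal(back$imu$fs_imu, 100)
  expect_identical(back$emg$samples, rec$emg$samples)
})

test_that("stream alignment intersects spans and trims streams", {
  emg <- make_emg(n = 3 * 2000, fs = 2000, t0 = 0)
  imu <- make_imu(n = 3 * 100, fs = 100, t0 = 0)
  al <- align_streams(emg, imu)
  expect_equal(al$overlap_window, c(0, 299 / 100))

  imu_late <- make_imu(n = 4 * 100 + 1, fs = 100, t0 = 1)  # [1, 5]
  al2 <- align_streams(emg, imu_late)
  expect_equal(al2$overlap_window, c(1, 5999 / 2000), tolerance = 1e-9)
  # trimmed streams fully cover the window
  expect_gte(al2$emg$t0, 1 - 1e-9)
  expect_equal(nrow(al2$imu$acc),
               sum(1 + (0:400) / 100 <= 5999 / 2000 + 1e-12))

  expect_error(align_streams(make_emg(n = 400, fs = 2000),
                             make_imu(n = 20, fs = 100)),
               "overlap")
})

test_that("alignment is symmetric in the two streams' spans", {
  emg <- make_emg(n = 5000, fs = 2000, t0 = 0.3)   # [0.3, 2.8]
  imu <- make_imu(n = 250, fs = 100, t0 = 0.8)     # [0.8, 3.29]
  a <- align_streams(emg, imu)$overlap_window
  emg2 <- make_emg(n = 5000, fs = 2000, t0 = 0.8)
  imu2 <- make_imu(n = 250, fs = 100, t0 = 0.3)
  b <- align_streams(emg2, imu2)$overlap_window
  expect_equal(a[1], b[1])  # both = max of the two starts
})
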