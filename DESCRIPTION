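Package: strengthsense
Title: Upper-Limb Muscle Strength Assessment from sEMG and IMU Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An assessment pipeline for shoulder muscle strength grading from
    multichannel surface electromyography (sEMG) and inertial measurement unit
    (IMU) recordings. Provides Savitzky-Golay denoising and channel quality
    control, time- and frequency-domain sEMG features (RMS, iEMG, MAV, median
    frequency), complementary-filter fusion of accelerometer and gyroscope
    streams into roll/pitch/yaw, assembly and min-max normalization of a
    21-feature table, particle swarm optimization (PSO) of support vector
    regression and backpropagation neural network hyperparameters and weights
    (PSO-SVR, PSO-BPNN), a four-metric repeated-run evaluation harness with
    repeated-measures ANOVA and Bonferroni-corrected pairwise comparisons, and
    a synthetic-trial generator emulating a graded shoulder-flexion study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
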