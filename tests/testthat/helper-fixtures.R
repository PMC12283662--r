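# Fixture builders and independent oracles shared across the suite.

make_emg <- function(n = 4000, fs = 2000, seed = 1, subject = "S01",
                     trial = "T01", t0 = 0) {
  set.seed(seed)
  emg_trial(subject, trial, fs, matrix(rnorm(n * 3), n, 3), t0 = t0)
}

make_imu <- function(n = 300, fs = 100, seed = 1, subject = "S01",
                     trial = "T01", t0 = 0) {
  set.seed(seed)
  imu_trial(subject, trial, fs,
            acc = cbind(rnorm(n, 0, 0.01), rnorm(n, 0, 0.01),
                        1 + rnorm(n, 0, 0.01)),
            gyro = matrix(rnorm(n * 3), n, 3), t0 = t0)
}

make_record <- function(grade = 3, seed = 1, ...) {
  trial_record(make_emg(seed = seed, ...), make_imu(seed = seed + 1, ...),
               grade)
}

# Small desk-scale generator settings for structural tests.
small_sim_cfg <- function(...) {
  sim_config(n_subjects = 3L, trials_per_subject = 4L, fs_emg = 1000,
             trial_duration = 1.5, unusable_frac = 0, ...)
}

# Flat band-limited noise built in the frequency domain (unit magnitude in
# the band, random phases) -- an exactly flat-spectrum construction.
flat_band_noise <- function(n, fs, lo, hi, seed) {
  set.seed(seed)
  f <- (0:(n %/% 2)) * fs / n
  spec <- as.numeric(f >= lo & f <= hi) *
    exp(1i * runif(n %/% 2 + 1, 0, 2 * pi))
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(length(spec) - 1)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Brute-force moving least-squares oracle for Savitzky-Golay smoothing:
# an explicit degree-p polynomial regression on every full window, solved by
# QR, evaluated at the window centre.
polyfit_oracle <- function(x, window, p) {
  m <- (window - 1L) %/% 2L
  n <- length(x)
  D <- outer(-m:m, 0:p, "^")
  qrD <- qr(D)
  centre_row <- D[m + 1L, ]
  out <- rep(NA_real_, n)
  for (i in (m + 1L):(n - m)) {
    beta <- qr.coef(qrD, x[(i - m):(i + m)])
    out[i] <- sum(centre_row * beta)
  }
  out
}

# Independent epsilon-SVR oracle: solves the dual QP with kernlab::ipop and
# predicts with the resulting coefficients (never calls the implementation
# path). Minimizes 0.5 b'Hb + c'b over b = (alpha, alpha*) with
# sum(alpha - alpha*) = 0, 0 <= b <= C.
svr_qp_oracle <- function(X, y, C, gamma, epsilon, X_new = X) {
  n <- nrow(X)
  K <- exp(-gamma * as.matrix(stats::dist(X))^2)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cvec <- c(epsilon - y, epsilon + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  sol <- kernlab::ipop(cvec, H, A, b = 0, l = rep(0, 2 * n),
                       u = rep(C, 2 * n), r = 0, sigf = 9, maxiter = 200)
  beta <- kernlab::primal(sol)
  coef <- beta[1:n] - beta[(n + 1):(2 * n)]
  fx0 <- as.numeric(K %*% coef)
  free_lo <- which(beta[1:n] > 1e-6 * C & beta[1:n] < C * (1 - 1e-6))
  free_hi <- which(beta[(n + 1):(2 * n)] > 1e-6 * C &
                   beta[(n + 1):(2 * n)] < C * (1 - 1e-6))
  b_off <- if (length(free_lo) || length(free_hi))
    mean(c(y[free_lo] - epsilon - fx0[free_lo],
           y[free_hi] + epsilon - fx0[free_hi]))
  else mean(y - fx0)
  Kn <- exp(-gamma * (outer(rowSums(X_new^2), rep(1, n)) +
                      outer(rep(1, nrow(X_new)), rowSums(X^2)) -
                      2 * X_new %*% t(X)))
  as.numeric(Kn %*% coef) + b_off
}
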