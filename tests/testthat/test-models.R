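toy_xy <- function(n = 60, d = 3, seed = 5) {
  set.seed(seed)
  X <- matrix(runif(n * d), n, d)
  y <- 2.5 + sin(2 * pi * X[, 1]) + 0.5 * X[, 2]
  list(X = X, y = y)
}

test_that("SVR matches an independent dual-QP solution on tiny sets", {
  skip_if_not_installed("kernlab")
  # 1-D five-point set
  X1 <- matrix(c(0, 0.25, 0.5, 0.75, 1))
  y1 <- c(0, 0.3, 0.8, 0.6, 0.2)
  m1 <- train_svr(X1, y1, C = 10, gamma = 0.5, epsilon = 0.05)
  Xq <- matrix(seq(0, 1, 0.125))
  expect_equal(predict(m1, Xq),
               svr_qp_oracle(X1, y1, 10, 0.5, 0.05, Xq),
               tolerance = 1e-4)
  # 2-D six-point set
  set.seed(6)
  X2 <- matrix(runif(12), 6, 2)
  y2 <- rnorm(6)
  m2 <- train_svr(X2, y2, C = 5, gamma = 1, epsilon = 0.1)
  expect_equal(predict(m2, X2), svr_qp_oracle(X2, y2, 5, 1, 0.1),
               tolerance = 1e-4)
})

test_that("targets inside the tube give the flat zero-slack solution", {
  set.seed(2)
  X <- matrix(runif(20), 10, 2)
  m <- train_svr(X, rep(3.7, 10))
  expect_equal(predict(m, X), rep(3.7, 10))
  # epsilon wider than the target range -> constant mid-range fit
  y <- 3 + runif(10, 0, 0.15)
  m2 <- train_svr(X, y, epsilon = 0.2)
  expect_equal(predict(m2, X), rep(mean(range(y)), 10))
  expect_true(all(abs(y - predict(m2, X)) <= 0.2 + 1e-12))
})

test_that("the network represents an affine map almost exactly", {
  set.seed(1)
  X <- matrix(runif(50), 50, 1)
  y <- 3 * X[, 1] + 1
  m <- train_bpnn(X, y, max_iter = 3000, seed = 2)
  r2 <- regression_metrics(y, predict(m, X))["r2"]
  expect_gte(r2, 0.99)
})

test_that("constant targets give near-constant predictions", {
  set.seed(3)
  X <- matrix(runif(60), 20, 3)
  m <- train_bpnn(X, rep(4, 20), seed = 1)
  expect_equal(predict(m, X), rep(4, 20), tolerance = 0.05)
})

test_that("all four trainers are seed-deterministic end to end", {
  dat <- toy_xy()
  Xn <- apply_norm(dat$X, fit_norm(dat$X))
  m1 <- train_bpnn(Xn, dat$y, seed = 7)
  m2 <- train_bpnn(Xn, dat$y, seed = 7)
  expect_identical(m1$theta, m2$theta)
  expect_false(identical(m1$theta, train_bpnn(Xn, dat$y, seed = 8)$theta))

  p1 <- train_pso_bpnn(Xn, dat$y, n_iters = 10L, seed = 7)
  p2 <- train_pso_bpnn(Xn, dat$y, n_iters = 10L, seed = 7)
  expect_identical(p1$theta, p2$theta)

  s1 <- train_pso_svr(Xn, dat$y, n_particles = 4L, n_iters = 8L, seed = 7)
  s2 <- train_pso_svr(Xn, dat$y, n_particles = 4L, n_iters = 8L, seed = 7)
  expect_identical(c(s1$C, s1$gamma), c(s2$C, s2$gamma))
  expect_identical(predict(s1, Xn), predict(s2, Xn))
})

test_that("PSO-tuned SVR is never worse than the reference configuration", {
  dat <- toy_xy(seed = 5)
  Xn <- apply_norm(dat$X, fit_norm(dat$X))
  tuned <- train_pso_svr(Xn, dat$y, n_particles = 6L, n_iters = 15L,
                         seed = 3)
  fold_id <- kfold_assign(nrow(Xn), 5, seed = 3 + 1L)
  ref_cv <- strengthsense:::svr_cv_rmse(Xn, dat$y, 10, 0.1, 0.1, fold_id)
  expect_lte(tuned$cv_rmse, ref_cv + 1e-12)
})

test_that("the PSO phase dominates its initial swarm and BP only descends", {
  dat <- toy_xy(seed = 9)
  Xn <- apply_norm(dat$X, fit_norm(dat$X))
  m <- train_pso_bpnn(Xn, dat$y, n_iters = 25L, seed = 5)
  expect_lte(m$pso_mse, m$trace[1])        # gbest dominates initial swarm
  expect_true(all(diff(m$trace) <= 0))
  expect_lte(m$train_mse, m$pso_mse)       # fine-tune never worsens MSE
})

test_that("prediction is batch-consistent and survives save/load", {
  dat <- toy_xy(seed = 12)
  Xn <- apply_norm(dat$X, fit_norm(dat$X))
  m <- train_svr(Xn, dat$y)
  single <- vapply(seq_len(8), function(i)
    predict(m, Xn[i, , drop = FALSE]), numeric(1))
  expect_equal(predict(m, Xn[1:8, ]), single)

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_identical(predict(load_model(path), Xn), predict(m, Xn))

  expect_error(predict(m, Xn[, 1:2]), "feature columns")
  # clipping flag restricts predictions to the MMT range
  mb <- train_bpnn(Xn, dat$y * 3, seed = 1, max_iter = 10L)
  expect_true(all(predict(mb, Xn, clip = TRUE) >= 2 &
                  predict(mb, Xn, clip = TRUE) <= 5))
})
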