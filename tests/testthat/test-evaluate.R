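test_that("the four metrics match hand-evaluated closed forms", {
  m <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(unname(m["r2"]), 0, tolerance = 1e-12)
  expect_equal(unname(m["rmse"]), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(m["mae"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m["mbe"]), 0, tolerance = 1e-12)

  a <- c(2, 3.5, 5, 4)
  p0 <- regression_metrics(a, a)
  expect_equal(unname(p0), c(1, 0, 0, 0))

  # constant offset: mbe = actual - predicted = -0.5 under the stated sign
  poff <- regression_metrics(a, a + 0.5)
  expect_equal(unname(poff[c("rmse", "mae", "mbe")]), c(0.5, 0.5, -0.5))
  expect_equal(unname(regression_metrics(a, a + 0.5,
                                         flip_mbe_sign = TRUE)["mbe"]), 0.5)

  expect_error(regression_metrics(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(regression_metrics(1:3, 1:4), "equal-length")
})

test_that("rmse >= mae >= |mbe| and the R2 identity hold on random data", {
  for (seed in 1:20) {
    set.seed(seed)
    a <- rnorm(30, 3); p <- a + rnorm(30, sd = runif(1, 0.01, 2))
    m <- regression_metrics(a, p)
    expect_gte(m[["rmse"]], m[["mae"]])
    expect_gte(m[["mae"]], abs(m[["mbe"]]))
    pvar <- mean((a - mean(a))^2)
    expect_equal(m[["r2"]], 1 - m[["rmse"]]^2 / pvar, tolerance = 1e-12)
  }
})

test_that("RM-ANOVA agrees with aov and with the paired-t identity", {
  set.seed(42)
  mat <- matrix(rnorm(24, 3), 6, 4)  # 6 subjects x 4 models
  an <- rm_anova(mat)
  df <- data.frame(v = as.vector(mat),
                   model = factor(rep(1:4, each = 6)),
                   subject = factor(rep(1:6, 4)))
  ref <- summary(aov(v ~ model + subject, data = df))[[1]]
  expect_equal(an$F, ref["model", "F value"], tolerance = 1e-10)
  expect_equal(an$p, ref["model", "Pr(>F)"], tolerance = 1e-10)

  # for two models, F equals the square of the paired t statistic
  m2 <- mat[, 1:2]
  a2 <- rm_anova(m2)
  tt <- t.test(m2[, 1], m2[, 2], paired = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
})

test_that("identical model columns give F = 0 and adjusted p = 1", {
  v <- rnorm(8, 1)
  mat <- cbind(a = v, b = v, c = v)
  an <- rm_anova(mat)
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
})

test_that("the experiment harness is reproducible and correctly shaped", {
  set.seed(99)
  X <- matrix(runif(40 * 21), 40, 21)
  colnames(X) <- strengthsense:::feature_column_order()
  y <- 2 + 3 * X[, 1]
  tab <- structure(list(X = X, y = y,
                        subject_ids = rep(sprintf("S%02d", 1:8), each = 5),
                        column_names = colnames(X)),
                   class = "feature_table")
  # an exact linear model recovers y = f(X) perfectly on every split
  specs <- list(
    exact = function(X, y, seed) {
      fit <- lm.fit(cbind(1, X[, 1]), y)
      structure(list(coef = fit$coefficients), class = "exact_lm")
    },
    noisy = function(X, y, seed) {
      structure(list(mu = mean(y)), class = "mean_model")
    })
  assign("predict.exact_lm",
         function(object, newdata, ...)
           as.numeric(cbind(1, newdata[, 1]) %*% object$coef),
         envir = globalenv())
  assign("predict.mean_model",
         function(object, newdata, ...) rep(object$mu, nrow(newdata)),
         envir = globalenv())
  withr::defer({
    rm("predict.exact_lm", "predict.mean_model", envir = globalenv())
  })

  rep1 <- run_experiment(tab, specs, n_repeats = 4L, seed = 7)
  rep2 <- run_experiment(tab, specs, n_repeats = 4L, seed = 7)
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1$metrics), 8)      # 2 models x 4 repeats
  expect_equal(nrow(rep1$summary), 2)

  ex <- rep1$summary[rep1$summary$model == "exact", ]
  expect_equal(ex$r2_mean, 1, tolerance = 1e-9)
  expect_equal(ex$r2_sd, 0, tolerance = 1e-9)
  expect_equal(ex$rmse_mean, 0, tolerance = 1e-9)

  cmp <- compare_models(rep1)
  expect_equal(nrow(cmp$r2$pairwise), 1)
  expect_true(all(cmp$r2$pairwise$p_adj >= cmp$r2$pairwise$p_raw))
  ci <- cmp$rmse$ci
  expect_true(all(ci$lower <= ci$mean & ci$mean <= ci$upper))
})

test_that("four models produce six Bonferroni-scaled comparisons", {
  set.seed(5)
  metrics <- do.call(rbind, lapply(c("m1", "m2", "m3", "m4"), function(m)
    data.frame(model = m, repeat_id = 1:6, r2 = rnorm(6, 0.8, 0.05),
               rmse = rnorm(6, 0.3, 0.05), mae = rnorm(6, 0.25, 0.04),
               mbe = rnorm(6, 0, 0.02))))
  report <- structure(list(metrics = metrics, summary = NULL,
                           n_repeats = 6L, seed = 5L),
                      class = "eval_report")
  cmp <- compare_models(report, metrics = "r2")
  pw <- cmp$r2$pairwise
  expect_equal(nrow(pw), 6)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 6))
})
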