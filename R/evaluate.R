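#' Regression metric set
#'
#' The four-metric panel used to compare the strength regressors:
#' \itemize{
#'   \item `r2` -- coefficient of determination,
#'     `1 - sum((a - p)^2) / sum((a - mean(a))^2)`;
#'   \item `rmse` -- root mean squared error (grade units);
#'   \item `mae` -- mean absolute error (grade units);
#'   \item `mbe` -- mean bias error, `mean(actual - predicted)` (signed;
#'     under this convention a negative MBE means over-prediction --
#'     `flip_mbe_sign = TRUE` gives the predicted-minus-actual convention).
#' }
#'
#' @param actual,predicted Equal-length numeric vectors; `actual` must not be
#'   constant (R-squared undefined).
#' @param flip_mbe_sign Report `mean(predicted - actual)` instead.
#' @return Named numeric vector `c(r2, rmse, mae, mbe)`.
#' @export
regression_metrics <- function(actual, predicted, flip_mbe_sign = FALSE) {
  if (length(actual) != length(predicted) || length(actual) == 0L)
    stopf("actual and predicted must be equal-length, non-empty")
  if (stats::var(actual) == 0)
    stopf("constant actual values: R-squared undefined")
  err <- actual - predicted
  mbe <- mean(err)
  c(r2 = 1 - sum(err^2) / sum((actual - mean(actual))^2),
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    mbe = if (flip_mbe_sign) -mbe else mbe)
}

default_model_specs <- function() {
  list(
    bpnn = function(X, y, seed) train_bpnn(X, y, seed = seed),
    svr = function(X, y, seed) train_svr(X, y),
    pso_bpnn = function(X, y, seed) train_pso_bpnn(X, y, seed = seed),
    pso_svr = function(X, y, seed) train_pso_svr(X, y, seed = seed)
  )
}

#' Repeated-run model comparison experiment
#'
#' For each repeat: a fresh seeded 7:3 trial split of the feature table,
#' min-max normalization fitted on the training partition, all models
#' trained on identical partitions, and the four test-set metrics recorded.
#' Per-repeat seeds fan out from `seed` by a fixed counter scheme
#' (`seed + 7919 * repeat`), so the whole report is reproducible from the
#' single master seed.
#'
#' @param table A `feature_table` from [assemble_features()].
#' @param model_specs Named list of trainers `function(X, y, seed)`; default
#'   the four reference models (BPNN, SVR, PSO-BPNN, PSO-SVR).
#' @param n_repeats Number of repeats (>= 2 for SDs; default 10).
#' @param seed Master seed.
#' @param train_fraction Training fraction (default 0.7).
#' @param norm_on_all Fit normalization on all rows before splitting (the
#'   leakier convention; default `FALSE`).
#' @return An object of class `eval_report`: list with `metrics` (long
#'   data.frame: model, repeat, r2, rmse, mae, mbe), `summary` (mean and SD
#'   per model per metric), `n_repeats`, `seed`.
#' @export
run_experiment <- function(table, model_specs = default_model_specs(),
                           n_repeats = 10L, seed = 42L,
                           train_fraction = 0.7, norm_on_all = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (n_repeats < 2L) stopf("n_repeats must be at least 2 for SDs")
  if (is.null(names(model_specs)) || any(names(model_specs) == ""))
    stopf("model_specs must be a named list")
  rows <- list()
  for (r in seq_len(n_repeats)) {
    rs <- seed + 7919L * r
    sp <- split_indices(nrow(table$X), train_fraction, seed = rs)
    ns <- if (norm_on_all) fit_norm(table$X)
          else fit_norm(table$X[sp$train, , drop = FALSE])
    Xtr <- apply_norm(table$X[sp$train, , drop = FALSE], ns)
    Xte <- apply_norm(table$X[sp$test, , drop = FALSE], ns)
    ytr <- table$y[sp$train]; yte <- table$y[sp$test]
    for (m in names(model_specs)) {
      fit <- model_specs[[m]](Xtr, ytr, rs)
      met <- regression_metrics(yte, stats::predict(fit, Xte))
      rows[[length(rows) + 1L]] <-
        data.frame(model = m, repeat_id = r, t(met))
    }
  }
  metrics <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(metrics$model), function(m) {
    sub <- metrics[metrics$model == m, c("r2", "rmse", "mae", "mbe")]
    data.frame(model = m,
               t(setNames(as.numeric(rbind(colMeans(sub),
                                           apply(sub, 2, stats::sd))),
                          as.vector(t(outer(names(sub), c("mean", "sd"),
                                            paste, sep = "_"))))))
  }))
  structure(list(metrics = metrics, summary = summ,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("<eval_report> %d models x %d repeats (seed %d)\n",
              length(unique(x$metrics$model)), x$n_repeats, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s R2 %.4f +/- %.4f  RMSE %.4f +/- %.4f  MAE %.4f +/- %.4f  MBE %+.4f +/- %.4f\n",
                s$model[i], s$r2_mean[i], s$r2_sd[i], s$rmse_mean[i],
                s$rmse_sd[i], s$mae_mean[i], s$mae_sd[i], s$mbe_mean[i],
                s$mbe_sd[i]))
  invisible(x)
}

#' One-way repeated-measures ANOVA from sums of squares
#'
#' Models are the within factor, repeats (or folds) the subjects:
#' `SS_total` is partitioned into `SS_subjects`, `SS_models` and residual;
#' `F = MS_models / MS_error` with `(k-1, (k-1)(n-1))` degrees of freedom.
#' No sphericity correction is applied.
#'
#' @param mat Numeric matrix `[n_subjects x k_models]` of a metric.
#' @return List with `F`, `df1`, `df2`, `p`, and the sums of squares.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L || n < 3L)
    stopf("repeated-measures ANOVA needs >= 2 models and >= 3 observations")
  grand <- mean(mat)
  ss_total <- sum((mat - grand)^2)
  ss_subjects <- k * sum((rowMeans(mat) - grand)^2)
  ss_models <- n * sum((colMeans(mat) - grand)^2)
  ss_error <- max(0, ss_total - ss_subjects - ss_models)
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  tol <- 1e-12 * max(ss_total, 1)
  Fv <- if (ss_error <= tol) {
    if (ss_models <= tol) 0 else Inf  # no residual variance
  } else (ss_models / df1) / (ss_error / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       ss_models = ss_models, ss_subjects = ss_subjects,
       ss_error = ss_error)
}

#' Statistical comparison of the evaluated models
#'
#' For each requested metric: repeated-measures ANOVA across models (repeats
#' as subjects), Bonferroni-corrected pairwise paired t-tests (raw p times
#' `k(k-1)/2`, capped at 1), and a 95% Student-t confidence interval per
#' model mean.
#'
#' @param report An `eval_report` from [run_experiment()].
#' @param metrics Metric columns to test (default `c("r2", "rmse")`).
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return Named list per metric with elements `anova`, `pairwise`
#'   (data.frame with `p_raw`, `p_adj`), `ci` (data.frame with mean and
#'   bounds).
#' @export
compare_models <- function(report, metrics = c("r2", "rmse"),
                           conf_level = 0.95) {
  stopifnot(inherits(report, "eval_report"))
  models <- unique(report$metrics$model)
  k <- length(models)
  out <- list()
  for (met in metrics) {
    mat <- sapply(models, function(m)
      report$metrics[report$metrics$model == m, met])
    an <- rm_anova(mat)
    pairs <- utils::combn(models, 2)
    m_corr <- k * (k - 1) / 2
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- mat[, pairs[1, j]]; b <- mat[, pairs[2, j]]
      if (stats::sd(a - b) == 0) {  # degenerate pair: no paired variance
        tv <- if (mean(a - b) == 0) 0 else Inf * sign(mean(a - b))
        pv <- if (mean(a - b) == 0) 1 else 0
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        tv <- unname(tt$statistic); pv <- tt$p.value
      }
      data.frame(model_a = pairs[1, j], model_b = pairs[2, j],
                 mean_diff = mean(a - b), t = tv, p_raw = pv,
                 p_adj = min(1, pv * m_corr))
    }))
    alpha <- 1 - conf_level
    ci <- do.call(rbind, lapply(models, function(m) {
      v <- mat[, m]
      se <- stats::sd(v) / sqrt(length(v))
      tq <- stats::qt(1 - alpha / 2, length(v) - 1)
      data.frame(model = m, mean = mean(v), lower = mean(v) - tq * se,
                 upper = mean(v) + tq * se)
    }))
    out[[met]] <- list(anova = an, pairwise = pw, ci = ci)
  }
  out
}
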