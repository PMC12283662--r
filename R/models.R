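new_strength_model <- function(kind, predict_fn_fields, extra = list()) {
  structure(c(list(kind = kind), predict_fn_fields, extra),
            class = "strength_model")
}

# epsilon-insensitive RBF SVR with explicit handling of the degenerate case:
# when the whole target range fits inside the 2*epsilon tube, w = 0 with a
# flat f(x) = mid-range is the exact zero-slack optimum (and the fitter
# rejects such problems as "empty").
svr_fit <- function(X, y, C, gamma, epsilon) {
  if (diff(range(y)) <= 2 * epsilon) {
    return(list(constant = mean(range(y)), fit = NULL))
  }
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = C, gamma = gamma, epsilon = epsilon,
                    scale = FALSE, tolerance = 1e-6)
  list(constant = NULL, fit = fit)
}

svr_predict <- function(obj, X) {
  if (!is.null(obj$constant)) rep(obj$constant, nrow(X))
  else as.numeric(stats::predict(obj$fit, X))
}

check_predict_input <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stopf("model expects %d feature columns, got %d", model$n_features,
          ncol(X))
  X
}

#' Train a backpropagation neural-network regressor
#'
#' Single hidden layer of `hidden` tanh units with a linear output, trained
#' by full-batch gradient-descent backpropagation on squared error for up to
#' `max_iter` epochs (targets are centred internally; the mean is restored
#' at prediction). The descent is monitored: a loss-increasing step is
#' reverted with a halved learning rate, so training error is non-increasing.
#'
#' @param X Normalized feature matrix `[n x d]`.
#' @param y Numeric target vector (MMT grades).
#' @param hidden Hidden-layer width (default 5).
#' @param max_iter Maximum training epochs (default 1000).
#' @param learning_rate Initial gradient-descent step (default 0.01).
#' @param seed Integer seed for weight initialization.
#' @return A `strength_model` of kind `"bpnn"`.
#' @export
train_bpnn <- function(X, y, hidden = 5L, max_iter = 1000L,
                       learning_rate = 0.01, seed = 1L) {
  X <- as.matrix(X)
  if (hidden < 1L || max_iter < 1L) stopf("hidden and max_iter must be >= 1")
  y_center <- mean(y)
  theta <- mlp_init(ncol(X), hidden, seed)
  res <- mlp_descend(theta, X, y - y_center, hidden, max_iter, learning_rate)
  new_strength_model("bpnn",
                     list(theta = res$theta, hidden = as.integer(hidden),
                          y_center = y_center, n_features = ncol(X)),
                     list(train_mse = res$loss, seed = seed))
}

#' Train an epsilon-insensitive support vector regressor
#'
#' RBF-kernel SVR: deviations inside the `epsilon` tube incur no loss, larger
#' ones are penalized linearly at weight `C` against the flatness of the
#' regression function. Defaults are the reference configuration
#' (`C = 10`, `gamma = 0.1`, `epsilon = 0.1`).
#'
#' @inheritParams train_bpnn
#' @param C Penalty (regularization) parameter, `> 0`.
#' @param gamma RBF kernel coefficient, `> 0`.
#' @param epsilon Tube half-width, `>= 0`.
#' @return A `strength_model` of kind `"svr"`.
#' @export
train_svr <- function(X, y, C = 10, gamma = 0.1, epsilon = 0.1) {
  X <- as.matrix(X)
  if (C <= 0 || gamma <= 0 || epsilon < 0)
    stopf("require C > 0, gamma > 0, epsilon >= 0")
  obj <- svr_fit(X, y, C, gamma, epsilon)
  new_strength_model("svr",
                     list(svr = obj, n_features = ncol(X)),
                     list(C = C, gamma = gamma, epsilon = epsilon))
}

svr_cv_rmse <- function(X, y, C, gamma, epsilon, fold_id) {
  sq <- 0
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    obj <- svr_fit(X[tr, , drop = FALSE], y[tr], C, gamma, epsilon)
    pred <- svr_predict(obj, X[!tr, , drop = FALSE])
    sq <- sq + sum((y[!tr] - pred)^2)
  }
  sqrt(sq / length(y))
}

#' PSO-tuned support vector regressor
#'
#' A particle swarm searches the `(C, gamma)` box (optionally including
#' `epsilon`) minimizing five-fold cross-validated RMSE on the training
#' partition; the final model is refit on the full training set at the swarm
#' best. Raw training RMSE is available as the fitness instead
#' (`fitness = "train"`), but it drives `C` to its bound and overfits.
#' Defaults follow the reference setting: 10 particles, 100 iterations,
#' `c1 = c2 = 1.7`, bounds `C` in `[1, 100]`, `gamma` in `[0.001, 1]`.
#'
#' @inheritParams train_svr
#' @param bounds `[2 x 2]` (or `[3 x 2]` with `include_epsilon`) box bounds,
#'   rows `(C, gamma[, epsilon])`.
#' @param n_particles,n_iters,c1,c2,omega Swarm settings (see
#'   [pso_config()]).
#' @param folds Cross-validation folds for the fitness (default 5).
#' @param fitness `"cv"` (default) or `"train"`.
#' @param include_epsilon Also search the tube half-width (default `FALSE`).
#' @param seed Integer seed (swarm and fold assignment).
#' @return A `strength_model` of kind `"pso_svr"` carrying the tuned
#'   parameters and the convergence `trace`.
#' @export
train_pso_svr <- function(X, y, bounds = rbind(C = c(1, 100),
                                               gamma = c(0.001, 1)),
                          n_particles = 10L, n_iters = 100L,
                          c1 = 1.7, c2 = 1.7, omega = 0.7, folds = 5L,
                          fitness = c("cv", "train"),
                          include_epsilon = FALSE, epsilon = 0.1,
                          seed = 1L) {
  X <- as.matrix(X)
  fitness <- match.arg(fitness)
  if (include_epsilon && nrow(bounds) < 3L)
    bounds <- rbind(bounds, epsilon = c(0.01, 0.5))
  fold_id <- kfold_assign(nrow(X), folds, seed = seed + 1L)
  fit_fn <- function(par) {
    eps <- if (include_epsilon) par[3] else epsilon
    if (fitness == "cv")
      svr_cv_rmse(X, y, par[1], par[2], eps, fold_id)
    else {
      obj <- svr_fit(X, y, par[1], par[2], eps)
      sqrt(mean((y - svr_predict(obj, X))^2))
    }
  }
  cfg <- pso_config(n_particles, n_iters, c1, c2, omega, bounds, seed)
  opt <- pso_optimize(fit_fn, cfg)
  # the tuned model is never worse than the reference configuration under
  # the tuning fitness when the reference lies inside the search box
  ref <- c(10, 0.1, epsilon)[seq_len(nrow(bounds))]
  if (all(ref >= bounds[, 1] & ref <= bounds[, 2])) {
    ref_fit <- fit_fn(ref)
    if (ref_fit < opt$value) {
      opt$par <- ref; opt$value <- ref_fit
    }
  }
  eps <- if (include_epsilon) opt$par[3] else epsilon
  obj <- svr_fit(X, y, opt$par[1], opt$par[2], eps)
  new_strength_model("pso_svr",
                     list(svr = obj, n_features = ncol(X)),
                     list(C = opt$par[1], gamma = opt$par[2], epsilon = eps,
                          cv_rmse = opt$value, trace = opt$trace,
                          seed = seed))
}

#' PSO-initialized backpropagation network
#'
#' A particle swarm first searches the network's flattened weight-and-bias
#' vector minimizing training MSE (global phase); backpropagation then
#' fine-tunes from the swarm best (local phase), combining PSO's global
#' search with gradient descent's local refinement. Defaults follow the
#' reference setting: 5 particles, 100 iterations, `c1 = c2 = 4.494` (a
#' setting above the classical stability bound, held stable here by the
#' optimizer's velocity and position clamping). The search box is the
#' per-layer weight-initialization region (input weights scaled by fan-in),
#' so the swarm explores well-conditioned, unsaturated networks -- the same
#' region single-start backpropagation initializes from.
#'
#' @inheritParams train_bpnn
#' @param n_particles,n_iters,c1,c2,omega Swarm settings.
#' @param weight_scale Multiplier on the per-layer initialization-scale
#'   search box (default 1).
#' @return A `strength_model` of kind `"pso_bpnn"` with the convergence
#'   `trace`.
#' @export
train_pso_bpnn <- function(X, y, hidden = 5L, n_particles = 5L,
                           n_iters = 100L, c1 = 4.494, c2 = 4.494,
                           omega = 0.7, weight_scale = 1,
                           max_iter = 1000L, learning_rate = 0.01,
                           seed = 1L) {
  X <- as.matrix(X)
  y_center <- mean(y)
  yc <- y - y_center
  bounds <- mlp_weight_box(ncol(X), as.integer(hidden), weight_scale)
  cfg <- pso_config(n_particles, n_iters, c1, c2, omega, bounds, seed)
  opt <- pso_optimize(function(th) mlp_mse(th, X, yc, hidden), cfg)
  res <- mlp_descend(opt$par, X, yc, hidden, max_iter, learning_rate)
  new_strength_model("pso_bpnn",
                     list(theta = res$theta, hidden = as.integer(hidden),
                          y_center = y_center, n_features = ncol(X)),
                     list(train_mse = res$loss, pso_mse = opt$value,
                          trace = opt$trace, seed = seed))
}

#' Predict muscle-strength grades
#'
#' Deterministic predictions from a trained `strength_model`. Inputs must be
#' normalized with the same [fit_norm()] state as the training partition.
#' Predictions are not clipped to the MMT range by default.
#'
#' @param object A `strength_model`.
#' @param newdata Feature matrix with the model's column count.
#' @param clip Clip predictions to `[2, 5]` (default `FALSE`).
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.strength_model <- function(object, newdata, clip = FALSE, ...) {
  X <- check_predict_input(object, newdata)
  out <- switch(object$kind,
                bpnn = ,
                pso_bpnn = mlp_forward(object$theta, X, object$hidden) +
                  object$y_center,
                svr = ,
                pso_svr = svr_predict(object$svr, X),
                stopf("unknown model kind '%s'", object$kind))
  if (clip) out <- pmin(pmax(out, 2), 5)
  out
}

#' @export
print.strength_model <- function(x, ...) {
  extra <- switch(x$kind,
                  svr = ,
                  pso_svr = sprintf("C=%.4g gamma=%.4g eps=%.3g", x$C,
                                    x$gamma, x$epsilon),
                  bpnn = ,
                  pso_bpnn = sprintf("%d hidden units, train MSE %.4g",
                                     x$hidden, x$train_mse))
  cat(sprintf("<strength_model:%s> %s\n", x$kind, extra))
  invisible(x)
}

#' Save / load a trained model
#'
#' Round-trips a `strength_model` through an RDS file; loaded models give
#' identical predictions.
#'
#' @param model A `strength_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "strength_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "strength_model"))
  m
}
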