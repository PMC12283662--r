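feature_column_order <- function(channels = c("anterior_deltoid",
                                              "middle_deltoid",
                                              "posterior_deltoid")) {
  c(as.vector(t(outer(channels, c("rms", "iemg", "mav", "mf"), paste,
                      sep = "_"))),
    "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
    "pitch", "roll", "yaw")
}

#' Assemble the n x 21 feature table from processed trials
#'
#' Runs the per-trial feature extractors over a list of [trial_record()]s:
#' streams are aligned, the sEMG is Savitzky-Golay denoised, the four sEMG
#' features are computed per deltoid channel (12 columns) and the nine IMU
#' scalars are appended (21 columns total). Trials flagged unusable are
#' dropped with a logged count; any non-finite feature aborts assembly naming
#' the trial and column.
#'
#' @param records List of [trial_record()]s.
#' @param window_length,polyorder Savitzky-Golay settings (see
#'   [sg_denoise()]).
#' @param K Complementary-filter coefficient.
#' @param use_device_angles Passed to [fuse_orientation()].
#' @param scalar_rule IMU reduction rule (see [imu_scalarize()]).
#' @param verbose Log the dropped-trial count (default `TRUE`).
#' @return An object of class `feature_table`: list with `X`
#'   (`[n x 21]` matrix), `y` (grades), `subject_ids`, `column_names`.
#' @export
assemble_features <- function(records, window_length = 51L, polyorder = 3L,
                              K = 0.4, use_device_angles = FALSE,
                              scalar_rule = "peak", verbose = TRUE) {
  if (length(records) == 0L) stopf("no trials to assemble")
  usable <- vapply(records, function(r) isTRUE(r$usable), logical(1))
  if (verbose && any(!usable))
    message(sprintf("dropping %d unusable trial(s); %d remain",
                    sum(!usable), sum(usable)))
  records <- records[usable]
  if (length(records) == 0L) stopf("no usable trials to assemble")
  cols <- feature_column_order(records[[1L]]$emg$channels)
  rows <- lapply(records, function(rec) {
    al <- align_streams(rec$emg, rec$imu)
    emg <- sg_denoise(al$emg, window_length, polyorder)
    fe <- emg_features(emg)
    orient <- fuse_orientation(al$imu, K = K,
                               use_device_angles = use_device_angles)
    fi <- imu_scalarize(al$imu, orient, rule = scalar_rule)
    v <- c(fe, fi)[cols]
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("trial %s/%s: non-finite feature '%s'", rec$emg$subject_id,
            rec$emg$trial_id, cols[bad[1L]])
    v
  })
  X <- do.call(rbind, rows)
  colnames(X) <- cols
  structure(list(X = X,
                 y = vapply(records, function(r) r$grade, numeric(1)),
                 subject_ids = vapply(records,
                                      function(r) r$emg$subject_id,
                                      character(1)),
                 column_names = cols),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trials x %d features, grades %g-%g\n",
              nrow(x$X), ncol(x$X), min(x$y), max(x$y)))
  invisible(x)
}

#' Fit min-max normalization state
#'
#' Records the per-column minimum and maximum of the fitting partition for
#' the linear rescaling `x' = (x - Min) / (Max - Min)`, which removes unit
#' heterogeneity across the 21 features. Fit on the training partition only
#' and apply to test data (values outside the training range map outside
#' `[0, 1]`); labels are never normalized.
#'
#' @param X Numeric feature matrix (training partition).
#' @return An object of class `norm_state` with fields `min`, `max`.
#' @export
fit_norm <- function(X) {
  check_numeric_matrix(X, "X")
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max),
                 columns = colnames(X)),
            class = "norm_state")
}

#' Apply a fitted min-max normalization
#'
#' @param X Numeric matrix with the same columns as the fitting partition.
#' @param state A `norm_state` from [fit_norm()].
#' @return Rescaled matrix. Degenerate columns (`Max == Min` in the fit) map
#'   to 0 with a warning.
#' @export
apply_norm <- function(X, state) {
  stopifnot(inherits(state, "norm_state"))
  check_numeric_matrix(X, "X")
  if (ncol(X) != length(state$min)) stopf("column count mismatch")
  rng <- state$max - state$min
  degen <- rng <= 0
  if (any(degen)) {
    warning(sprintf("degenerate column(s) %s mapped to 0",
                    paste(which(degen), collapse = ", ")), call. = FALSE)
    rng[degen] <- 1
  }
  out <- sweep(sweep(X, 2, state$min), 2, rng, "/")
  out[, degen] <- 0
  out
}

#' Seeded 7:3 train/test split
#'
#' Reproducible shuffled row split: `floor(train_fraction * n)` rows go to
#' the training partition (145 rows at the default 0.7 give 101), the rest to
#' test. Splitting is by trial; `group_by` can name a grouping vector (e.g.
#' subject ids) to keep groups intact, since pooled trial-level splitting of
#' repeated measures inflates apparent performance.
#'
#' @param n Number of rows.
#' @param train_fraction Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @param group_by Optional grouping vector of length `n`.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_indices <- function(n, train_fraction = 0.7, seed = 1L,
                          group_by = NULL) {
  if (n < 10L) stopf("too few rows (%d) for a meaningful split", n)
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  if (is.null(group_by)) {
    perm <- with_seed(seed, sample.int(n))
    n_train <- floor(train_fraction * n)
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[(n_train + 1L):n]))
  } else {
    stopifnot(length(group_by) == n)
    groups <- unique(group_by)
    gperm <- with_seed(seed, sample(groups))
    sizes <- cumsum(vapply(gperm, function(g) sum(group_by == g),
                           numeric(1)))
    k <- which(sizes >= train_fraction * n)[1L]
    train_groups <- gperm[seq_len(k)]
    idx <- which(group_by %in% train_groups)
    list(train = sort(idx), test = sort(setdiff(seq_len(n), idx)))
  }
}

#' Seeded k-fold assignment
#'
#' Disjoint, exhaustive, near-equal folds (145 rows into 5 folds of 29) from
#' a seeded shuffle.
#'
#' @param n Number of rows.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of length `n` with fold labels `1..folds`.
#' @export
kfold_assign <- function(n, folds = 5L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) stopf("folds must be at least 2")
  if (n < folds) stopf("n = %d too small for %d folds", n, folds)
  perm <- with_seed(seed, sample.int(n))
  assign <- integer(n)
  assign[perm] <- rep_len(seq_len(folds), n)
  assign
}
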