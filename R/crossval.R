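# Nested cross-validation: outer 10-fold testing, inner
# leave-one-training-fold-out hyperparameter tuning, fold-model averaging.
# All fitting and scoring at full scale runs on per-fold covariance
# sufficient statistics accumulated trial-by-trial (lagged samples never
# cross trial boundaries, and the concatenated design is never formed).

#' Assign trials to cross-validation folds
#'
#' Seeded permutation of trials into `n_folds` folds of near-equal size
#' (sizes differ by at most one).  Trials, not samples, are the assignment
#' unit.
#'
#' @param n_trials Number of trials (>= `n_folds`).
#' @param n_folds Number of folds (default 10).
#' @param seed Seed; the same seed reproduces the assignment.
#' @return A `trf_folds`: list with `assignment` (fold index per trial,
#'   1..n_folds) and `n_folds`.
#' @export
make_folds <- function(n_trials, n_folds = 10L, seed = 1L) {
  n_trials <- as.integer(n_trials); n_folds <- as.integer(n_folds)
  if (n_trials < n_folds) {
    stop_invalid("`n_trials` (", n_trials, ") must be >= `n_folds` (", n_folds, ")")
  }
  perm <- with_seed(seed, sample.int(n_trials))
  assignment <- integer(n_trials)
  assignment[perm] <- rep_len(seq_len(n_folds), n_trials)
  structure(list(assignment = assignment, n_folds = n_folds, seed = seed),
            class = "trf_folds")
}

# Training-only normalization statistics for a dataset: EEG stats per
# channel over the concatenated training trials; envelope stats from the
# ATTENDED training envelopes (the convention for the stimulus feature).
training_norm_stats <- function(dataset, train_idx) {
  eeg_all <- do.call(rbind, lapply(dataset$trials[train_idx],
                                   function(tr) tr$eeg$samples))
  env_all <- unlist(lapply(dataset$trials[train_idx], function(tr) {
    if (tr$attended == "A") tr$envA$samples[, 1] else tr$envB$samples[, 1]
  }))
  fs <- dataset$trials[[1]]$eeg$fs
  list(
    eeg = norm_stats(time_series(eeg_all, fs = fs,
                                 channel_labels = dataset$trials[[1]]$eeg$labels)),
    env = norm_stats(time_series(env_all, fs = fs, channel_labels = "envelope"))
  )
}

#' Normalize one trial with training statistics
#'
#' Applies training-fold normalization statistics (as stored per outer fold
#' in a `trf_cv` result under `$norm`) to a raw trial: EEG channels through
#' the EEG statistics, both envelopes through the attended-envelope
#' statistics.
#'
#' @param trial A trial list (`eeg`, `envA`, `envB`, `attended`).
#' @param norm Normalization pair (`eeg`, `env`) of `trf_norm` objects.
#' @return The normalized trial.
#' @export
normalize_trial <- function(trial, norm) {
  list(eeg = znormalize(trial$eeg, norm$eeg),
       envA = znormalize(trial$envA, norm$env),
       envB = znormalize(trial$envB, norm$env),
       attended = trial$attended)
}

# Regressor/target split for one normalized trial.
trial_xy <- function(trial, direction) {
  env_att <- if (trial$attended == "A") trial$envA else trial$envB
  if (direction == "forward") list(x = env_att, y = trial$eeg)
  else list(x = trial$eeg, y = env_att)
}

# Per-fold covariance statistics for a dataset under one normalization.
fold_covariances <- function(dataset, folds, direction, spec, norm,
                             keep_raw = FALSE) {
  nf <- folds$n_folds
  stats <- vector("list", nf)
  raw <- if (keep_raw) replicate(nf, list(X = NULL, Y = NULL), simplify = FALSE)
  for (i in seq_along(dataset$trials)) {
    tr <- normalize_trial(dataset$trials[[i]], norm)
    xy <- trial_xy(tr, direction)
    d <- build_lagged_design(xy$x, spec)
    cv <- assemble_covariances(d, xy$y)
    f <- folds$assignment[i]
    stats[[f]] <- if (is.null(stats[[f]])) cv else
      combine_covariances(list(stats[[f]], cv))
    if (keep_raw) {
      raw[[f]]$X <- rbind(raw[[f]]$X, d$values)
      raw[[f]]$Y <- rbind(raw[[f]]$Y, xy$y$samples)
    }
  }
  list(stats = stats, raw = raw)
}

# Solve one estimator over a whole lambda path, sharing the spectral
# decomposition where possible.  Returns a list of weight matrices.
path_solutions <- function(estimator, cov, lambdas, alpha = 1,
                           n_channels = 1L, raw = NULL) {
  if (estimator == "ols") {
    # no hyperparameter: one Cholesky solve, shared across the "path"
    W <- solve_ols(cov)
    lapply(lambdas, function(l) W)
  } else if (estimator %in% c("ridge", "lra", "shrinkage")) {
    eig <- cov_eigen(cov)
    lapply(lambdas, function(l) {
      switch(estimator,
             ridge = solve_ridge(cov, l, eig = eig),
             lra = solve_lra(cov, l, eig = eig),
             shrinkage = solve_shrinkage(cov, l, eig = eig))
    })
  } else if (estimator == "tikhonov") {
    lapply(lambdas, function(l) solve_tikhonov(cov, l, n_channels = n_channels))
  } else if (estimator == "elasticnet") {
    if (is.null(raw)) {
      stop_invalid("Elastic Net tuning needs raw designs (keep_raw path)")
    }
    out <- vector("list", length(lambdas))
    w0 <- NULL
    for (i in seq_along(lambdas)) {
      fit <- solve_elastic_net(raw$X, raw$Y, lambda = lambdas[i],
                               alpha = alpha, w_init = w0)
      w0 <- fit$W_std
      out[[i]] <- fit$W
    }
    out
  } else stop_invalid("unknown estimator ", estimator)
}

#' Tune the regularization parameter by inner cross-validation
#'
#' Leave-one-training-fold-out tuning: for every inner fold, models are fit
#' at each path value on the remaining training folds and scored by the
#' validation correlation on the held-out fold (channel-mean for
#' multi-output models).  The selected lambda maximizes the across-fold
#' mean validation correlation (smallest lambda on ties, since validation
#' curves are typically flat); the returned model is the element-wise mean
#' of the inner-fold models at that lambda.
#'
#' @param fold_stats List of per-training-fold `trf_cov` statistics
#'   (at least 2).
#' @param estimator Estimator name.
#' @param path A `trf_path`.
#' @param alpha Elastic Net balance.
#' @param n_channels Regressor channel count (Tikhonov penalty layout).
#' @param fold_raw Optional per-fold raw `list(X, Y)` (Elastic Net only).
#' @return List: `lambda`, `model` (averaged weight matrix), `mean_curve`
#'   (validation correlation per path value), `curve` (folds x path
#'   matrix), `lambdas`.
#' @export
tune_lambda_nested <- function(fold_stats, estimator, path, alpha = 1,
                               n_channels = 1L, fold_raw = NULL) {
  nf <- length(fold_stats)
  if (nf < 2L) stop_invalid("need at least 2 inner folds to tune")
  lambdas <- path$lambdas
  curve <- matrix(NA_real_, nf, length(lambdas))
  sols <- vector("list", nf)
  for (v in seq_len(nf)) {
    train <- combine_covariances(fold_stats[-v])
    raw_train <- if (!is.null(fold_raw)) {
      list(X = do.call(rbind, lapply(fold_raw[-v], `[[`, "X")),
           Y = do.call(rbind, lapply(fold_raw[-v], `[[`, "Y")))
    }
    Ws <- path_solutions(estimator, train, lambdas, alpha = alpha,
                         n_channels = n_channels, raw = raw_train)
    sols[[v]] <- Ws
    curve[v, ] <- vapply(Ws, function(W) {
      mean(cor_from_stats(W, fold_stats[[v]]), na.rm = TRUE)
    }, numeric(1))
  }
  mean_curve <- colMeans(curve)
  if (all(!is.finite(mean_curve))) {
    stop_invalid("tuning failure: all validation correlations undefined")
  }
  best <- which(mean_curve >= max(mean_curve, na.rm = TRUE) - 1e-15)[1]
  W_avg <- Reduce(`+`, lapply(sols, `[[`, best)) / nf
  list(lambda = lambdas[best], model = W_avg, mean_curve = mean_curve,
       curve = curve, lambdas = lambdas)
}

#' Forward-model regression accuracy
#'
#' Pearson correlation per EEG channel between the model prediction from
#' the attended envelope and the actual EEG, reduced by the channel mean
#' (default), the channel maximum, or returned per channel.  Zero-variance
#' channels are excluded with a warning.
#'
#' @param model A forward `trf_model`.
#' @param envelope Attended-envelope `trf_ts` (normalized as in training).
#' @param eeg EEG `trf_ts` from held-out data.
#' @param mode `"mean"`, `"max"`, or `"per_channel"`.
#' @return Scalar or per-channel vector of correlations.
#' @export
regression_accuracy_forward <- function(model, envelope, eeg,
                                        mode = c("mean", "max", "per_channel")) {
  mode <- match.arg(mode)
  d <- build_lagged_design(envelope, model$lag_spec)
  pred <- apply_model(model, d)
  r <- vapply(seq_len(n_channels(eeg)), function(j) {
    p <- pred$samples[, j]; y <- eeg$samples[, j]
    if (stats::var(p) == 0 || stats::var(y) == 0) NA_real_ else stats::cor(p, y)
  }, numeric(1))
  if (anyNA(r)) {
    warning(sum(is.na(r)), " zero-variance channel(s) excluded from accuracy",
            call. = FALSE)
  }
  switch(mode,
         mean = mean(r, na.rm = TRUE),
         max = max(r, na.rm = TRUE),
         per_channel = r)
}

#' Backward-model regression accuracy
#'
#' Pearson correlation between the attended envelope and its EEG-based
#' reconstruction.
#'
#' @param model A backward `trf_model`.
#' @param eeg EEG `trf_ts` from held-out data.
#' @param attended_env Attended-envelope `trf_ts`.
#' @return Scalar correlation.
#' @export
regression_accuracy_backward <- function(model, eeg, attended_env) {
  d <- build_lagged_design(eeg, model$lag_spec)
  recon <- apply_model(model, d)
  pearson_r(recon$samples[, 1], attended_env$samples[, 1])
}

#' Nested cross-validated model estimation and testing
#'
#' The full nested procedure on a `trf_dataset`: for each outer test fold,
#' training-fold normalization statistics are estimated, per-fold
#' covariances assembled, the regularization parameter tuned by inner
#' leave-one-training-fold-out cross-validation, the inner-fold models
#' averaged, and the averaged model scored on the held-out fold.
#'
#' @param dataset A `trf_dataset`.
#' @param direction `"forward"` or `"backward"`.
#' @param estimator Estimator name.
#' @param path `trf_path` of regularization values (`NULL` for the
#'   estimator's default path).
#' @param alpha Elastic Net balance.
#' @param folds A `trf_folds` (or `NULL` to draw one from `seed`).
#' @param n_folds,seed Fold layout when `folds` is `NULL`.
#' @param outer_folds Outer folds to evaluate (default: all).
#' @param kernel_s Kernel length in seconds (default 0.5).
#' @return A `trf_cv` report: per-outer-fold list with `lambda`,
#'   `mean_curve`, `model` (a `trf_model`), `r_attended`, `r_unattended`,
#'   plus `folds`, and fold-mean `r_attended`.
#' @export
cross_validate <- function(dataset, direction = c("backward", "forward"),
                           estimator = "ridge", path = NULL, alpha = 1,
                           folds = NULL, n_folds = 10L, seed = 1L,
                           outer_folds = NULL, kernel_s = 0.5) {
  direction <- match.arg(direction)
  stopifnot(inherits(dataset, "trf_dataset"))
  fs <- dataset$trials[[1]]$eeg$fs
  spec <- default_lag_spec(direction, fs, kernel_s)
  folds <- folds %||% make_folds(length(dataset$trials), n_folds, seed)
  outer_folds <- outer_folds %||% seq_len(folds$n_folds)
  path <- path %||% default_lambda_path(estimator, alpha)
  nch_x <- if (direction == "backward") n_channels(dataset$trials[[1]]$eeg) else 1L
  need_raw <- estimator == "elasticnet"
  results <- vector("list", length(outer_folds))
  for (k in seq_along(outer_folds)) {
    test_fold <- outer_folds[k]
    train_idx <- which(folds$assignment != test_fold)
    norm <- training_norm_stats(dataset, train_idx)
    fc <- fold_covariances(dataset, folds, direction, spec, norm,
                           keep_raw = need_raw)
    train_folds <- setdiff(seq_len(folds$n_folds), test_fold)
    tuned <- tune_lambda_nested(fc$stats[train_folds], estimator, path,
                                alpha = alpha, n_channels = nch_x,
                                fold_raw = if (need_raw) fc$raw[train_folds])
    model <- linear_model(tuned$model, direction = direction, spec = spec,
                          fs = fs, n_inputs = nch_x)
    r_att <- mean(cor_from_stats(tuned$model, fc$stats[[test_fold]]),
                  na.rm = TRUE)
    # unattended reference: correlate against the other stream's envelope
    r_unatt <- local({
      rs <- vapply(which(folds$assignment == test_fold), function(i) {
        tr <- normalize_trial(dataset$trials[[i]], norm)
        env_un <- if (tr$attended == "A") tr$envB else tr$envA
        if (direction == "backward") {
          regression_accuracy_backward(model, tr$eeg, env_un)
        } else {
          regression_accuracy_forward(model, env_un, tr$eeg)
        }
      }, numeric(1))
      fisher_mean(rs)
    })
    results[[k]] <- list(test_fold = test_fold, lambda = tuned$lambda,
                         mean_curve = tuned$mean_curve,
                         lambdas = tuned$lambdas, model = model,
                         norm = norm, r_attended = r_att,
                         r_unattended = r_unatt)
  }
  structure(list(fold_results = results, folds = folds,
                 direction = direction, estimator = estimator,
                 alpha = alpha, kernel_s = kernel_s,
                 r_attended = fisher_mean(vapply(results, `[[`, numeric(1),
                                                 "r_attended")),
                 r_unattended = fisher_mean(vapply(results, `[[`, numeric(1),
                                                   "r_unattended"))),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf(
    "<trf_cv> %s %s: %d outer fold(s), r_attended = %.3f, r_unattended = %.3f\n",
    x$direction, x$estimator, length(x$fold_results), x$r_attended,
    x$r_unattended))
  invisible(x)
}
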