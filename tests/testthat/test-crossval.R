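# Nested cross-validation: folds, tuning, leakage, scoring.

test_that("fold assignment is balanced, seeded, and trial-based", {
  f <- make_folds(60, 10, seed = 5)
  expect_identical(sort(unique(f$assignment)), 1:10)
  expect_true(all(table(f$assignment) == 6))
  expect_identical(make_folds(60, 10, seed = 5)$assignment, f$assignment)
  expect_false(identical(make_folds(60, 10, seed = 6)$assignment,
                         f$assignment))
  # remainder rule: 61 trials -> nine folds of 6, one of 7
  sizes <- sort(as.integer(table(make_folds(61, 10, seed = 1)$assignment)))
  expect_identical(sizes, c(rep(6L, 9), 7L))
  expect_error(make_folds(5, 10), ">=")
})

test_that("suffstat correlations equal direct correlations", {
  # the pooled-correlation shortcut must agree with literally predicting
  # and correlating
  set.seed(3)
  X <- matrix(rnorm(300 * 4), 300, 4)
  Y <- cbind(X %*% rnorm(4) + rnorm(300), rnorm(300))
  d <- build_lagged_design(time_series(X, fs = 1), lag_spec(0L, 0L))
  cv <- assemble_covariances(d, time_series(Y, fs = 1))
  W <- matrix(rnorm(8), 4, 2)
  r_stats <- trfdecode:::cor_from_stats(W, cv)
  pred <- X %*% W
  expect_equal(r_stats, c(cor(pred[, 1], Y[, 1]), cor(pred[, 2], Y[, 2])),
               tolerance = 1e-12)
})

test_that("lambda tuning selects a helpful penalty on noisy data", {
  ds <- small_dataset()   # 20 x 20 s, 16 channels, -10 dB
  folds <- make_folds(20, 5, seed = 9)
  spec <- default_lag_spec("backward", 64)
  norm <- trfdecode:::training_norm_stats(ds, which(folds$assignment != 1))
  fc <- trfdecode:::fold_covariances(ds, folds, "backward", spec, norm)
  path <- sweep_geometric_lambdas(1e-4, 6, 10)
  tuned <- tune_lambda_nested(fc$stats[2:5], "ridge", path)
  expect_true(tuned$lambda %in% path$lambdas)
  expect_gt(tuned$lambda, path$lambdas[1])
  # test accuracy at the tuned lambda is at least that of the path minimum
  train <- combine_covariances(fc$stats[2:5])
  W_min <- solve_ridge(train, path$lambdas[1])
  W_sel <- solve_ridge(train, tuned$lambda)
  r_min <- mean(trfdecode:::cor_from_stats(W_min, fc$stats[[1]]))
  r_sel <- mean(trfdecode:::cor_from_stats(W_sel, fc$stats[[1]]))
  expect_gte(r_sel, r_min - 1e-9)
  # a singleton path short-circuits but still averages inner folds
  t1 <- tune_lambda_nested(fc$stats[2:5], "ridge",
                           trfdecode:::new_path(0.5, "geometric"))
  expect_identical(t1$lambda, 0.5)
  expect_error(tune_lambda_nested(fc$stats[1], "ridge", path), "2 inner")
})

test_that("no test-fold sample influences training or tuning", {
  ds <- small_dataset(n_trials = 8L, duration_s = 6, n_channels = 4L,
                      seed = 23L)
  cv1 <- cross_validate(ds, "backward", "ridge", n_folds = 4L, seed = 4,
                        outer_folds = 1L,
                        path = sweep_geometric_lambdas(1e-4, 10, 4))
  # perturb every trial of the held-out fold
  ds2 <- ds
  for (i in which(cv1$folds$assignment == 1L)) {
    ds2$trials[[i]]$eeg$samples <- ds2$trials[[i]]$eeg$samples +
      matrix(rnorm(length(ds2$trials[[i]]$eeg$samples)), nrow =
               nrow(ds2$trials[[i]]$eeg$samples))
  }
  cv2 <- cross_validate(ds2, "backward", "ridge", n_folds = 4L, seed = 4,
                        outer_folds = 1L,
                        path = sweep_geometric_lambdas(1e-4, 10, 4))
  expect_identical(cv1$fold_results[[1]]$model$weights,
                   cv2$fold_results[[1]]$model$weights)
  expect_identical(cv1$fold_results[[1]]$lambda, cv2$fold_results[[1]]$lambda)
  # ...but the test-fold score does change
  expect_false(identical(cv1$r_attended, cv2$r_attended))
})

test_that("cross-validation is reproducible given seed and data", {
  ds <- small_dataset(n_trials = 8L, duration_s = 6, n_channels = 4L,
                      seed = 23L)
  a <- cross_validate(ds, "backward", "shrinkage", n_folds = 4L, seed = 4,
                      outer_folds = 1L,
                      path = sweep_logsigmoid_lambdas(1e-4, 2, 5))
  b <- cross_validate(ds, "backward", "shrinkage", n_folds = 4L, seed = 4,
                      outer_folds = 1L,
                      path = sweep_logsigmoid_lambdas(1e-4, 2, 5))
  expect_identical(a$fold_results[[1]]$lambda, b$fold_results[[1]]$lambda)
  expect_identical(a$r_attended, b$r_attended)
})

test_that("forward accuracy modes are ordered and exact on ground truth", {
  ds <- small_dataset(n_trials = 6L, duration_s = 8, n_channels = 5L,
                      snr_db = Inf, seed = 29L, gain_unattended = 0)
  model <- true_forward_model(ds)
  tr <- ds$trials[[1]]
  env <- time_series(drop(scale(tr$envA$samples[, 1])), fs = 64)
  r_pc <- regression_accuracy_forward(model, env, tr$eeg, mode = "per_channel")
  expect_equal(r_pc, rep(1, 5), tolerance = 1e-10)
  # mode ordering on noisy data
  dsn <- small_dataset(n_trials = 6L, duration_s = 8, n_channels = 5L,
                       snr_db = -5, seed = 29L)
  mn <- true_forward_model(dsn)
  trn <- dsn$trials[[1]]
  envn <- time_series(drop(scale(trn$envA$samples[, 1])), fs = 64)
  expect_gte(regression_accuracy_forward(mn, envn, trn$eeg, mode = "max"),
             regression_accuracy_forward(mn, envn, trn$eeg, mode = "mean"))
})

test_that("backward accuracy is the reconstruction correlation", {
  ds <- small_dataset(n_trials = 6L, duration_s = 8, n_channels = 5L,
                      seed = 31L)
  tr <- ds$trials[[1]]
  env <- tr$envA
  # a model that reproduces the envelope exactly gives r = 1 and its
  # negation gives r = -1
  spec <- lag_spec(0L, 0L)
  d <- build_lagged_design(tr$eeg, spec)
  # synth: regress envelope on instantaneous EEG via OLS for a nontrivial model
  cv <- assemble_covariances(d, env)
  W <- solve_ridge(cv, 1)
  m <- linear_model(W, "backward", spec, fs = 64, n_inputs = 5L)
  r <- regression_accuracy_backward(m, tr$eeg, env)
  m_neg <- linear_model(-W, "backward", spec, fs = 64, n_inputs = 5L)
  expect_equal(regression_accuracy_backward(m_neg, tr$eeg, env), -r)
  expect_lte(abs(r), 1)
})

test_that("backward reconstruction beats the forward channel mean", {
  # backward models filter the channel noise out; forward models must
  # predict it, so their channel-mean accuracy sits lower
  ds <- small_dataset(n_trials = 10L, duration_s = 10, n_channels = 8L,
                      snr_db = -10, seed = 37L)
  fb <- cross_validate(ds, "backward", "ridge", n_folds = 5L, seed = 6,
                       outer_folds = 1L,
                       path = sweep_geometric_lambdas(1e-4, 10, 5))
  ff <- cross_validate(ds, "forward", "ridge", n_folds = 5L, seed = 6,
                       outer_folds = 1L,
                       path = sweep_geometric_lambdas(1e-4, 10, 5))
  expect_gt(fb$r_attended, ff$r_attended)
})

test_that("averaged fold models are usually at least as good as the worst
           inner model", {
  wins <- 0L
  for (s in 1:9) {
    ds <- small_dataset(n_trials = 8L, duration_s = 6, n_channels = 4L,
                        snr_db = -8, seed = 100L + s)
    folds <- make_folds(8, 4, seed = s)
    spec <- default_lag_spec("backward", 64)
    norm <- trfdecode:::training_norm_stats(ds, which(folds$assignment != 1))
    fc <- trfdecode:::fold_covariances(ds, folds, "backward", spec, norm)
    path <- trfdecode:::new_path(10, "geometric")
    tuned <- tune_lambda_nested(fc$stats[2:4], "ridge", path)
    r_avg <- mean(trfdecode:::cor_from_stats(tuned$model, fc$stats[[1]]))
    r_single <- vapply(2:4, function(v) {
      W <- solve_ridge(combine_covariances(fc$stats[setdiff(2:4, v)]), 10)
      mean(trfdecode:::cor_from_stats(W, fc$stats[[1]]))
    }, numeric(1))
    if (r_avg >= min(r_single) - 1e-12) wins <- wins + 1L
  }
  expect_gt(wins, 4L)   # majority across seeds
})
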