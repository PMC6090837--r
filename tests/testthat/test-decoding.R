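# Attention classification, ROC, information transfer rates, noise floor.

make_decisions <- function(n = 200, sep = 1, seed = 1) {
  set.seed(seed)
  label <- rep(c("A", "B"), length.out = n)
  decision <- rnorm(n, mean = ifelse(label == "A", sep / 2, -sep / 2))
  list(decision = decision, label = label)
}

test_that("segment windows respect trial bounds and the kernel span", {
  ds <- small_dataset(n_trials = 2L, duration_s = 50, n_channels = 4L,
                      seed = 41L)
  spec <- default_lag_spec("backward", 64)
  W <- matrix(rnorm(33 * 4), 33 * 4, 1)
  m <- linear_model(W, "backward", spec, fs = 64, n_inputs = 4L)
  tr <- ds$trials[[1]]
  seg30 <- segment_correlation_features(m, tr$eeg, tr$envA, tr$envB,
                                        tr$attended, seg_len_s = 30)
  expect_identical(nrow(seg30), 21L)     # floor((50-30)/1) + 1
  seg_full <- segment_correlation_features(m, tr$eeg, tr$envA, tr$envB,
                                           tr$attended, seg_len_s = 50)
  expect_identical(nrow(seg_full), 1L)
  expect_error(segment_correlation_features(m, tr$eeg, tr$envA, tr$envB,
                                            tr$attended, seg_len_s = 0.25),
               "kernel")
})

test_that("argmax classification follows the correlation difference", {
  out <- classify_argmax(c(0.2, 0.1, 0.3), c(0.1, 0.1, 0.5))
  expect_equal(out$decision, c(0.1, 0, -0.2))
  expect_identical(out$predicted, c("A", "A", "B"))
  expect_identical(out$tie, c(FALSE, TRUE, FALSE))
  # swapping streams negates the decision value
  swapped <- classify_argmax(c(0.1, 0.1, 0.5), c(0.2, 0.1, 0.3))
  expect_equal(swapped$decision, -out$decision)
})

test_that("the linear SVM separates and respects label symmetry", {
  set.seed(2)
  n <- 60
  lab <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 4, mean = ifelse(lab == "A", 1.5, -1.5)), n, 4)
  fit <- train_forward_classifier(X, lab)
  dv <- predict_decision_values(fit, X)
  expect_identical(ifelse(dv >= 0, "A", "B"), lab)      # separable: acc 1
  # class-swapped training data negates the decision values
  fit_sw <- train_forward_classifier(X, ifelse(lab == "A", "B", "A"))
  dv_sw <- predict_decision_values(fit_sw, X)
  expect_equal(dv_sw, -dv, tolerance = 1e-6)
  # 132-dimensional feature vectors (2 x 66 channels) are accepted
  X132 <- matrix(rnorm(40 * 132), 40, 132)
  X132[1:20, 1:66] <- X132[1:20, 1:66] + 1
  fit132 <- train_forward_classifier(X132, rep(c("A", "B"), each = 20))
  expect_length(predict_decision_values(fit132, X132), 40L)
  expect_error(train_forward_classifier(X, rep("A", n)), "both classes")
})

test_that("ROC endpoints, monotonicity, and accuracy consistency hold", {
  d <- make_decisions(300, sep = 1.5, seed = 3)
  roc <- roc_from_decisions(d$decision, d$label)
  expect_equal(roc$tpr[1], 0); expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1); expect_equal(roc$fpr[nrow(roc)], 1)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$fraction) >= 0))
  # accuracy recovered from the ROC at threshold zero equals the fraction
  # of correctly signed decisions
  pa <- mean(d$label == "A")
  i0 <- max(which(roc$threshold > 0))
  acc_roc <- roc$tpr[i0] * pa + (1 - roc$fpr[i0]) * (1 - pa)
  expect_equal(acc_roc, mean((d$decision >= 0) == (d$label == "A")),
               tolerance = 1e-12)
  # perfect separation: AUC = 1
  perf <- roc_from_decisions(ifelse(d$label == "A", 1, -1) + 0.01 * rnorm(300),
                             d$label)
  expect_equal(roc_auc(perf), 1)
  # label-independent decisions: AUC near 1/2
  null <- make_decisions(2000, sep = 0, seed = 4)
  expect_lt(abs(roc_auc(roc_from_decisions(null$decision, null$label)) - 0.5),
            0.05)
  expect_error(roc_from_decisions(rnorm(5), rep("A", 5)), "one class")
})

test_that("our AUC agrees with an independent implementation", {
  d <- make_decisions(150, sep = 1, seed = 5)
  ours <- roc_auc(roc_from_decisions(d$decision, d$label))
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = d$label, predictor = d$decision, levels = c("B", "A"),
    direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("Wolpaw ITR matches its closed forms", {
  expect_equal(wolpaw_itr(0.5, 2, 10), 0)
  expect_equal(wolpaw_itr(1, 2, 2), 2)
  expect_equal(wolpaw_itr(0.9, 2, 1),
               1 + 0.9 * log2(0.9) + 0.1 * log2(0.1))   # ~0.531
  expect_equal(wolpaw_itr(0.9, 2, 1), 0.531, tolerance = 1e-3)
  # binary closed form V (1 - H(P)) on a grid
  P <- seq(0.5, 1, by = 0.05)
  H <- ifelse(P %in% c(0, 1), 0, -P * log2(P) - (1 - P) * log2(1 - P))
  H[P == 1] <- 0
  expect_equal(wolpaw_itr(P, 2, 3), 3 * (1 - H), tolerance = 1e-12)
  # strictly increasing above chance
  grid <- wolpaw_itr(seq(0.51, 1, by = 0.01), 2, 1)
  expect_true(all(diff(grid) > 0))
  expect_error(wolpaw_itr(1.2, 2, 1), "\\[0, 1\\]")
})

test_that("Nykopp ITR is an upper bound reached by withholding", {
  # a perfect classifier with everything retained transmits exactly V bits
  lab <- rep(c("A", "B"), 50)
  perfect <- ifelse(lab == "A", 1, -1) * runif(100, 0.5, 1)
  it <- nykopp_itr(perfect, lab, V = 2)
  expect_equal(it$nykopp, 2, tolerance = 1e-9)
  expect_equal(it$wolpaw, 2, tolerance = 1e-9)
  # label-independent decisions carry (almost) no information
  null <- make_decisions(800, sep = 0, seed = 6)
  it0 <- nykopp_itr(null$decision, null$label, V = 1)
  perm_bound <- quantile(vapply(1:40, function(i) {
    set.seed(1000 + i)
    nykopp_itr(null$decision, sample(null$label), V = 1)$nykopp
  }, numeric(1)), 0.99)
  expect_lte(it0$nykopp, perm_bound * 1.5 + 0.05)
  # Nykopp dominates Wolpaw across separability levels and seeds
  for (s in 1:6) {
    d <- make_decisions(240, sep = c(0.5, 1, 2)[1 + s %% 3], seed = 10 + s)
    it <- nykopp_itr(d$decision, d$label, V = 2)
    expect_gte(it$nykopp, it$wolpaw - 1e-9)
  }
})

test_that("class separability returns the defined moments", {
  r_att <- c(0.3, 0.5, 0.4, 0.6)
  expect_equal(class_separability(r_att, r_att)$mean_difference, 0)
  shifted <- class_separability(r_att + 0.2, r_att)
  expect_equal(shifted$mean_difference, 0.2)
  expect_equal(shifted$within_class_sd, sd(r_att) * sqrt(1))
  # with equal mean separation, the lower-spread feature classifies better
  set.seed(7)
  lab <- rep(c("A", "B"), each = 500)
  mu <- ifelse(lab == "A", 0.5, -0.5)
  tight <- rnorm(1000, mu, 0.4)
  loose <- rnorm(1000, mu, 1.2)
  acc_tight <- mean((tight >= 0) == (lab == "A"))
  acc_loose <- mean((loose >= 0) == (lab == "A"))
  expect_gt(acc_tight, acc_loose)
})

test_that("phase randomization preserves the power spectrum exactly", {
  set.seed(8)
  for (n in c(256, 255)) {
    x <- rnorm(n)
    y <- phase_randomize(x, seed = 2)
    expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-8)
    expect_false(isTRUE(all.equal(x, y)))
    expect_true(all(abs(Im(fft(y)[1])) < 1e-8))
  }
})

test_that("the noise floor interval brackets zero on null data", {
  ds <- small_dataset(n_trials = 4L, duration_s = 10, n_channels = 4L,
                      snr_db = -Inf, seed = 47L)
  spec <- default_lag_spec("backward", 64)
  set.seed(9)
  W <- matrix(rnorm(33 * 4, sd = 0.1), 33 * 4, 1)
  m <- linear_model(W, "backward", spec, fs = 64, n_inputs = 4L)
  nf <- noise_floor(m, ds$trials, n_randomizations = 60L, seed = 3)
  expect_lt(nf$ci[1], 0)
  expect_gt(nf$ci[2], 0)
  # near-symmetric null distribution
  expect_lt(abs(nf$ci[1] + nf$ci[2]), 2.5 * diff(nf$ci))
  expect_warning(noise_floor(m, ds$trials[1:2], n_randomizations = 10L,
                             seed = 1), "unreliable")
})

test_that("accuracy does not degrade with longer decoding segments", {
  wins <- 0L
  for (s in 1:5) {
    ds <- small_dataset(n_trials = 6L, duration_s = 20, n_channels = 6L,
                        snr_db = -13, seed = 200L + s)
    cv <- cross_validate(ds, "backward", "ridge", n_folds = 3L, seed = s,
                         outer_folds = 1L,
                         path = trfdecode:::new_path(100, "geometric"))
    accs <- vapply(c(2, 6, 15), function(sl) {
      dec <- decode_segments(cv, ds, sl, 1)
      mean(dec$predicted == dec$label)
    }, numeric(1))
    if (all(diff(accs) >= -0.05)) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
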