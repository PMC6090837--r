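# Segment-wise attended-talker classification, ROC construction,
# Wolpaw/Nykopp information transfer rates, and the phase-randomization
# noise floor.

#' Segment-wise correlation features for attention classification
#'
#' Slides a window of `seg_len_s` seconds (stepped by `step_s`, never
#' crossing trial boundaries) over one trial and computes, per window, the
#' correlations on which classification rests.  The window duration
#' includes the kernel length, so correlations are computed over the
#' `seg_len - kernel` effective span whose predictions use only data inside
#' the window.
#'
#' Backward: the envelope is reconstructed from the EEG and correlated with
#' both stream envelopes (2 features per window).  Forward: the EEG is
#' predicted from each stream envelope and correlated with the actual EEG
#' per channel (2 x n_channels features per window).
#'
#' @param model A `trf_model`.
#' @param eeg,envA,envB Normalized `trf_ts` signals of one trial.
#' @param attended True label, `"A"` or `"B"`.
#' @param seg_len_s Window length in seconds (>= the kernel length).
#' @param step_s Window step in seconds (default 1).
#' @return For backward: data.frame with `segment`, `t0_s`, `label`, `r_a`,
#'   `r_b`.  For forward: list with `features` (windows x 2*n_channels),
#'   `label`, `t0_s`.
#' @export
segment_correlation_features <- function(model, eeg, envA, envB, attended,
                                         seg_len_s, step_s = 1) {
  stopifnot(inherits(model, "trf_model"))
  fs <- eeg$fs
  K <- n_lags(model$lag_spec)
  L <- as.integer(round(seg_len_s * fs))
  if (L < K) {
    stop_invalid("decoding window (", seg_len_s, " s) is shorter than the ",
                 "model kernel (", K / fs, " s)")
  }
  n <- n_samples(eeg)
  step <- max(1L, as.integer(round(step_s * fs)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  backward <- model$direction == "backward"
  # correlation span: predictions using only samples inside the window
  span_of <- function(t0) {
    if (backward) t0:(t0 + L - K) else (t0 + K - 1L):(t0 + L - 1L)
  }
  safe_r <- function(a, b) {
    if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  if (backward) {
    recon <- apply_model(model, build_lagged_design(eeg, model$lag_spec))
    ra <- rb <- numeric(length(starts))
    for (i in seq_along(starts)) {
      idx <- span_of(starts[i])
      ra[i] <- safe_r(recon$samples[idx, 1], envA$samples[idx, 1])
      rb[i] <- safe_r(recon$samples[idx, 1], envB$samples[idx, 1])
    }
    data.frame(segment = seq_along(starts), t0_s = (starts - 1L) / fs,
               label = attended, r_a = ra, r_b = rb)
  } else {
    predA <- apply_model(model, build_lagged_design(envA, model$lag_spec))
    predB <- apply_model(model, build_lagged_design(envB, model$lag_spec))
    nch <- n_channels(eeg)
    feats <- matrix(NA_real_, length(starts), 2L * nch)
    for (i in seq_along(starts)) {
      idx <- span_of(starts[i])
      for (j in seq_len(nch)) {
        feats[i, j] <- safe_r(predA$samples[idx, j], eeg$samples[idx, j])
        feats[i, nch + j] <- safe_r(predB$samples[idx, j], eeg$samples[idx, j])
      }
    }
    colnames(feats) <- c(paste0("rA_ch", seq_len(nch)),
                         paste0("rB_ch", seq_len(nch)))
    list(features = feats, label = attended, t0_s = (starts - 1L) / fs)
  }
}

#' Argmax attention classifier (backward models)
#'
#' Decision value `r_A - r_B`; label `"A"` when positive, `"B"` when
#' negative.  Exact ties break deterministically to `"A"` and are flagged.
#'
#' @param r_a,r_b Correlation features per segment.
#' @return Data.frame with `decision`, `predicted`, `tie`.
#' @export
classify_argmax <- function(r_a, r_b) {
  decision <- r_a - r_b
  data.frame(decision = decision,
             predicted = ifelse(decision >= 0, "A", "B"),
             tie = decision == 0)
}

#' Train the forward-model SVM attention classifier
#'
#' Maximum-margin linear classifier (hinge loss, soft-margin constant 1)
#' on the per-channel correlation features; features are used raw (they
#' are bounded in \[-1, 1\]).  The returned object predicts signed decision
#' values oriented so positive favors stream A.
#'
#' @param features Numeric matrix (segments x 2*n_channels).
#' @param labels Character vector of true labels (`"A"`/`"B"`).
#' @param cost Soft-margin constant (default 1).
#' @return A `trf_svm` with `decision_values(object, features)` semantics
#'   via [predict_decision_values()].
#' @export
train_forward_classifier <- function(features, labels, cost = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop_invalid("both classes must be present to train the classifier")
  }
  features <- as.matrix(features)
  keep <- stats::complete.cases(features)
  fit <- e1071::svm(features[keep, , drop = FALSE],
                    factor(labels[keep], levels = c("A", "B")),
                    kernel = "linear", cost = cost, scale = FALSE)
  # e1071 orients decision values toward the first label encountered;
  # record the sign that makes positive mean "A".
  sign_a <- if (fit$labels[1] == 1) 1 else -1
  structure(list(fit = fit, sign_a = sign_a), class = "trf_svm")
}

#' @rdname train_forward_classifier
#' @param object A `trf_svm`.
#' @param newdata Feature matrix.
#' @return Numeric decision values (positive = stream A).
#' @export
predict_decision_values <- function(object, newdata) {
  stopifnot(inherits(object, "trf_svm"))
  newdata <- as.matrix(newdata)
  newdata[!is.finite(newdata)] <- 0
  dv <- attr(stats::predict(object$fit, newdata, decision.values = TRUE),
             "decision.values")
  object$sign_a * as.numeric(dv)
}

#' ROC curve from decision records
#'
#' Sweeps the signed decision threshold over midpoints between sorted
#' distinct decision values (plus open endpoints), treating stream A as the
#' positive class.  Reports, per threshold, the true- and false-positive
#' rates of the rule `predict A when decision >= threshold`, and the
#' fraction of segments at or above the threshold.
#'
#' @param decisions Numeric decision values.
#' @param labels True labels (`"A"`/`"B"`).
#' @return A `trf_roc`: data.frame with `threshold`, `tpr`, `fpr`,
#'   `fraction`, and attribute `auc` (also via [roc_auc()]).
#' @export
roc_from_decisions <- function(decisions, labels) {
  labels <- as.character(labels)
  ok <- is.finite(decisions)
  decisions <- decisions[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L) {
    stop_invalid("degenerate ROC: only one class present")
  }
  v <- sort(unique(decisions))
  thr <- c(Inf, rev((v[-1] + v[-length(v)]) / 2), min(v) - 1)
  if (length(v) == 1L) thr <- c(Inf, v - 1)
  pos <- labels == "A"
  tpr <- vapply(thr, function(t) mean(decisions[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(decisions[!pos] >= t), numeric(1))
  frac <- vapply(thr, function(t) mean(decisions >= t), numeric(1))
  out <- data.frame(threshold = thr, tpr = tpr, fpr = fpr, fraction = frac)
  attr(out, "auc") <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  class(out) <- c("trf_roc", "data.frame")
  out
}

#' @rdname roc_from_decisions
#' @param roc A `trf_roc`.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Wolpaw information transfer rate
#'
#' `ITR_W = V * [log2 N + P log2 P + (1-P) log2((1-P)/(N-1))]` in bits per
#' minute, with the convention `0 * log2(0) = 0`.  Equals
#' `V * (1 - H(P))` for two balanced classes and is zero at chance.
#'
#' @param P Classifier accuracy in \[0, 1\].
#' @param N Number of classes (>= 2).
#' @param V Decision rate in trials per minute.
#' @return Bits per minute.
#' @export
wolpaw_itr <- function(P, N = 2L, V = 1) {
  if (any(P < 0 | P > 1)) stop_invalid("`P` must lie in [0, 1]")
  if (N < 2L) stop_invalid("`N` must be >= 2")
  xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)
  V * (log2(N) + xlog2(P) + ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0))
}

#' Nykopp information transfer rate
#'
#' Upper-bound ITR when low-confidence decisions may be withheld: sweeps a
#' threshold on the decision-function magnitude, builds the empirical
#' confusion matrix over retained segments, computes the mutual information
#' `sum_ij p(w_i) p(w-hat_j|w_i) log2 p(w-hat_j|w_i) - sum_j p(w-hat_j)
#' log2 p(w-hat_j)`, and returns the maximum over thresholds.  Thresholds
#' that leave only one true class are skipped.  `V` is the attempted-
#' segment rate as in the printed formula; set `scale_v_by_fraction` to
#' scale it by the retained fraction instead.
#'
#' @param decisions Signed decision values.
#' @param labels True labels (`"A"`/`"B"`).
#' @param V Decision rate in trials per minute.
#' @param scale_v_by_fraction Multiply `V` by the classified fraction
#'   (default `FALSE`).
#' @return A `trf_itr` list: `nykopp` (bits/min), `threshold`, `fraction`,
#'   `mutual_information`, plus the matched `wolpaw` value at threshold 0.
#' @export
nykopp_itr <- function(decisions, labels, V = 1, scale_v_by_fraction = FALSE) {
  labels <- as.character(labels)
  ok <- is.finite(decisions)
  decisions <- decisions[ok]; labels <- labels[ok]
  if (length(decisions) < 2L || length(unique(labels)) < 2L) {
    stop_invalid("need at least 2 segments covering both classes")
  }
  xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)
  mags <- sort(unique(abs(decisions)))
  thr <- c(0, (mags[-1] + mags[-length(mags)]) / 2)
  best <- list(mi = -Inf, threshold = 0, fraction = 1)
  for (t in thr) {
    keep <- abs(decisions) >= t
    if (!any(keep)) next
    lab <- labels[keep]
    pred <- ifelse(decisions[keep] >= 0, "A", "B")
    if (length(unique(lab)) < 2L) next      # guard: log of zero class prior
    pw <- c(A = mean(lab == "A"), B = mean(lab == "B"))
    mi <- 0
    phat <- c(A = mean(pred == "A"), B = mean(pred == "B"))
    for (i in c("A", "B")) {
      for (j in c("A", "B")) {
        pji <- mean(pred[lab == i] == j)
        mi <- mi + pw[[i]] * xlog2(pji)
      }
    }
    mi <- mi - sum(xlog2(phat))
    if (mi > best$mi) best <- list(mi = mi, threshold = t,
                                   fraction = mean(keep))
  }
  if (!is.finite(best$mi)) stop_invalid("no threshold retains both classes")
  v_eff <- if (scale_v_by_fraction) V * best$fraction else V
  acc <- mean((decisions >= 0) == (labels == "A"))
  structure(list(nykopp = v_eff * best$mi, threshold = best$threshold,
                 fraction = best$fraction, mutual_information = best$mi,
                 wolpaw = wolpaw_itr(acc, 2L, V), accuracy = acc, V = V),
            class = "trf_itr")
}

#' @export
print.trf_itr <- function(x, ...) {
  cat(sprintf(
    "<trf_itr> accuracy %.3f | Wolpaw %.3f, Nykopp %.3f bits/min (thr %.3g, %.0f%% classified)\n",
    x$accuracy, x$wolpaw, x$nykopp, x$threshold, 100 * x$fraction))
  invisible(x)
}

#' Class separability of correlation features
#'
#' The difference between class means `mean(r_attended) -
#' mean(r_unattended)` and the pooled within-class spread
#' `sqrt(0.5 * (var(r_attended) + var(r_unattended)))` of segment-wise
#' correlations.
#'
#' @param r_attended,r_unattended Segment correlations with the attended /
#'   unattended stream (>= 2 each).
#' @return List with `mean_difference` and `within_class_sd`.
#' @export
class_separability <- function(r_attended, r_unattended) {
  if (length(r_attended) < 2L || length(r_unattended) < 2L) {
    stop_invalid("need at least 2 segments per class")
  }
  list(mean_difference = mean(r_attended) - mean(r_unattended),
       within_class_sd = sqrt(0.5 * (stats::var(r_attended) +
                                       stats::var(r_unattended))))
}

#' Fourier phase randomization
#'
#' Replaces the phases of a real signal's Fourier transform with uniform
#' random phases (conjugate-symmetric, DC and Nyquist untouched), exactly
#' preserving the power spectrum.
#'
#' @param x Numeric vector.
#' @param seed Optional seed.
#' @return Phase-randomized vector of the same length.
#' @export
phase_randomize <- function(x, seed = NULL) {
  n <- length(x)
  run <- function() {
    X <- stats::fft(x)
    h <- (n - 1L) %/% 2L
    if (h >= 1L) {
      phi <- stats::runif(h, 0, 2 * pi)
      k <- seq_len(h)
      X[k + 1L] <- Mod(X[k + 1L]) * exp(1i * phi)
      X[n - k + 1L] <- Conj(X[k + 1L])
    }
    Re(stats::fft(X, inverse = TRUE) / n)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Phase-randomization noise floor for regression accuracy
#'
#' Holds a trained model fixed, phase-randomizes the regressor (the
#' envelope for a forward model, each EEG channel for a backward model) of
#' the supplied test trials, recomputes the regression accuracy, and
#' returns the empirical 95% interval of the null correlations.
#'
#' @param model A `trf_model`.
#' @param trials List of normalized trials (`eeg`, `envA`, `envB`,
#'   `attended`).
#' @param n_randomizations Number of randomizations (default 100; fewer
#'   than 20 warns that the interval is unreliable).
#' @param seed Seed for the randomization stream.
#' @return A `trf_noise_floor`: list with `r` (null accuracies), `ci`
#'   (2.5% and 97.5% quantiles), `n_randomizations`.
#' @export
noise_floor <- function(model, trials, n_randomizations = 100L, seed = 1L) {
  stopifnot(inherits(model, "trf_model"))
  if (n_randomizations < 20L) {
    warning("fewer than 20 randomizations: confidence interval unreliable",
            call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_randomizations)
  backward <- model$direction == "backward"
  r <- vapply(seq_len(n_randomizations), function(it) {
    rs <- vapply(trials, function(tr) {
      env_att <- if (tr$attended == "A") tr$envA else tr$envB
      if (backward) {
        shuf <- with_seed(seeds[it] + 0, {
          apply(tr$eeg$samples, 2L, phase_randomize)
        })
        eeg_r <- time_series(shuf, fs = tr$eeg$fs, channel_labels = tr$eeg$labels)
        regression_accuracy_backward(model, eeg_r, env_att)
      } else {
        env_r <- time_series(phase_randomize(env_att$samples[, 1],
                                             seed = seeds[it]),
                             fs = env_att$fs)
        regression_accuracy_forward(model, env_r, tr$eeg)
      }
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  structure(list(r = r,
                 ci = stats::quantile(r, c(0.025, 0.975), names = FALSE),
                 n_randomizations = n_randomizations),
            class = "trf_noise_floor")
}

#' @export
print.trf_noise_floor <- function(x, ...) {
  cat(sprintf("<trf_noise_floor> 95%% CI [%.4f, %.4f] from %d randomizations\n",
              x$ci[1], x$ci[2], x$n_randomizations))
  invisible(x)
}
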