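# Configuration-driven experiment orchestration: synthetic data (or a
# bundle on disk) -> nested cross-validation -> segment-wise attention
# decoding -> accuracy / ROC / ITR tables, with seeds and the resolved
# configuration logged into the result bundle.

default_experiment_config <- function() {
  list(
    data = list(type = "synthetic", scenario = list()),
    direction = "backward",
    estimator = "ridge",
    alpha = 1,
    lambda_path = NULL,          # NULL -> estimator default
    kernel_s = 0.5,
    n_folds = 10L,
    outer_folds = NULL,          # NULL -> all outer folds
    segment_lengths = c(1, 3, 5, 7, 10, 15, 20, 30),
    step_s = 1,
    seed = 1L,
    noise_floor_randomizations = 0L,
    outdir = NULL
  )
}

#' Read an experiment configuration file
#'
#' JSON or YAML (by extension); keys mirror the arguments of
#' [run_experiment()] and unknown keys are rejected.
#'
#' @param path Config file path.
#' @return Named list merged over the defaults.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(default_experiment_config())
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop_invalid("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  utils::modifyList(default_experiment_config(), cfg)
}

resolve_dataset <- function(data_cfg, seed) {
  type <- data_cfg$type %||% "synthetic"
  if (type == "synthetic") {
    sc_args <- data_cfg$scenario %||% list()
    if (is.null(sc_args$seed)) sc_args$seed <- seed
    generate_dataset(do.call(synthetic_scenario, sc_args))
  } else if (type == "bundle") {
    read_bundle(data_cfg$path)
  } else {
    stop_invalid("unknown data source type: ", type)
  }
}

#' Segment-wise attention decisions on the held-out folds
#'
#' Applies the fold models of a fitted cross-validation report to their
#' test folds at one decoding segment length: backward models classify by
#' argmax of the two stream correlations; forward models train the linear
#' SVM on the training/validation trials of each outer fold and apply it
#' to the test segments.
#'
#' @param cv A `trf_cv` from [cross_validate()].
#' @param dataset The `trf_dataset` the report was fit on.
#' @param seg_len_s Decoding segment length in seconds (includes the
#'   kernel length).
#' @param step_s Window step in seconds (default 1).
#' @return Data.frame of decision records: `trial`, `fold`, `segment`,
#'   `t0_s`, `label`, `decision`, `predicted`, `tie` (and `r_a`/`r_b` for
#'   backward models).
#' @export
decode_segments <- function(cv, dataset, seg_len_s, step_s = 1) {
  out <- list()
  for (fr in cv$fold_results) {
    test_idx <- which(cv$folds$assignment == fr$test_fold)
    train_idx <- which(cv$folds$assignment != fr$test_fold)
    if (cv$direction == "backward") {
      for (i in test_idx) {
        tr <- normalize_trial(dataset$trials[[i]], fr$norm)
        seg <- segment_correlation_features(fr$model, tr$eeg, tr$envA, tr$envB,
                                            tr$attended, seg_len_s, step_s)
        cls <- classify_argmax(seg$r_a, seg$r_b)
        out[[length(out) + 1L]] <- cbind(
          data.frame(trial = i, fold = fr$test_fold), seg, cls)
      }
    } else {
      collect <- function(idx) {
        feats <- list(); labs <- character(0); meta <- list()
        for (i in idx) {
          tr <- normalize_trial(dataset$trials[[i]], fr$norm)
          seg <- segment_correlation_features(fr$model, tr$eeg, tr$envA,
                                              tr$envB, tr$attended,
                                              seg_len_s, step_s)
          feats[[length(feats) + 1L]] <- seg$features
          labs <- c(labs, rep(seg$label, nrow(seg$features)))
          meta[[length(meta) + 1L]] <- data.frame(trial = i, t0_s = seg$t0_s)
        }
        list(features = do.call(rbind, feats), labels = labs,
             meta = do.call(rbind, meta))
      }
      tr_set <- collect(train_idx)
      te_set <- collect(test_idx)
      svm_fit <- train_forward_classifier(tr_set$features, tr_set$labels)
      dv <- predict_decision_values(svm_fit, te_set$features)
      out[[length(out) + 1L]] <- data.frame(
        trial = te_set$meta$trial, fold = fr$test_fold,
        segment = seq_along(dv), t0_s = te_set$meta$t0_s,
        label = te_set$labels, decision = dv,
        predicted = ifelse(dv >= 0, "A", "B"), tie = dv == 0)
    }
  }
  do.call(rbind, out)
}

#' Run a configured decoding experiment
#'
#' End-to-end: resolve the data source, run nested cross-validation for
#' the configured direction/estimator, classify attended talkers on the
#' held-out folds at every decoding segment length, and assemble accuracy,
#' ROC and information-transfer-rate tables.  With an `outdir`, the
#' resolved config, CV report, decisions and summary tables are written
#' out (JSON/CSV), making a run reproducible from its bundle alone.
#'
#' @param config Named list (see [read_experiment_config()]) or a path to a
#'   JSON/YAML config file.  Unspecified keys fall back to defaults.
#' @return A `trf_experiment`: list with `config`, `cv` (a `trf_cv`),
#'   `decisions` (per segment length), `accuracy` (data.frame), `itr`
#'   (data.frame), `roc` (for the longest segment length), optional
#'   `noise_floor`.
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- read_experiment_config(config)
  cfg <- utils::modifyList(default_experiment_config(), config)
  dataset <- resolve_dataset(cfg$data, cfg$seed)
  fs <- dataset$trials[[1]]$eeg$fs
  min_len <- cfg$kernel_s
  seg_lens <- cfg$segment_lengths[cfg$segment_lengths >= min_len]
  path <- cfg$lambda_path
  if (!is.null(path) && !inherits(path, "trf_path")) {
    path <- new_path(as.numeric(path$lambdas %||% path), path$family %||% "custom")
  }
  cv <- cross_validate(dataset, direction = cfg$direction,
                       estimator = cfg$estimator, path = path,
                       alpha = cfg$alpha, n_folds = cfg$n_folds,
                       seed = cfg$seed, outer_folds = cfg$outer_folds,
                       kernel_s = cfg$kernel_s)
  decisions <- list()
  acc_rows <- list()
  itr_rows <- list()
  for (sl in seg_lens) {
    dec <- decode_segments(cv, dataset, sl, cfg$step_s)
    decisions[[as.character(sl)]] <- dec
    correct <- dec$predicted == dec$label
    V <- 60 / sl                               # attempted decisions per minute
    # ITR needs both classes among the evaluated folds; a degenerate draw
    # (e.g. a single-class test fold) yields NA rather than a failed run
    itr <- if (length(unique(dec$label)) == 2L) {
      nykopp_itr(dec$decision, dec$label, V = V)
    } else {
      warning("single-class decision set at ", sl,
              " s segments: ITR not defined", call. = FALSE)
      list(wolpaw = NA_real_, nykopp = NA_real_, fraction = NA_real_)
    }
    acc_rows[[length(acc_rows) + 1L]] <- data.frame(
      segment_length_s = sl, n_segments = nrow(dec),
      accuracy = mean(correct))
    itr_rows[[length(itr_rows) + 1L]] <- data.frame(
      segment_length_s = sl, wolpaw_bits_min = itr$wolpaw,
      nykopp_bits_min = itr$nykopp, nykopp_fraction = itr$fraction)
  }
  longest <- as.character(max(seg_lens))
  roc <- if (length(unique(decisions[[longest]]$label)) == 2L) {
    roc_from_decisions(decisions[[longest]]$decision,
                       decisions[[longest]]$label)
  }
  nf <- NULL
  if (cfg$noise_floor_randomizations > 0L) {
    fr <- cv$fold_results[[1]]
    test_idx <- which(cv$folds$assignment == fr$test_fold)
    trials_n <- lapply(dataset$trials[test_idx], normalize_trial, norm = fr$norm)
    nf <- noise_floor(fr$model, trials_n,
                      n_randomizations = cfg$noise_floor_randomizations,
                      seed = cfg$seed)
  }
  result <- structure(list(
    config = cfg, cv = cv, decisions = decisions,
    accuracy = do.call(rbind, acc_rows), itr = do.call(rbind, itr_rows),
    roc = roc, noise_floor = nf,
    dataset_fingerprint = list(
      n_trials = length(dataset$trials), fs = fs,
      labels = dataset$labels, seed = cfg$seed)), class = "trf_experiment")
  if (!is.null(cfg$outdir)) write_experiment(result, cfg$outdir)
  result
}

#' @export
print.trf_experiment <- function(x, ...) {
  cat(sprintf("<trf_experiment> %s / %s\n", x$config$direction,
              x$config$estimator))
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}

write_experiment <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  cfg$lambda_path <- if (!is.null(cfg$lambda_path)) unclass(cfg$lambda_path)
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cv_report <- list(
    direction = result$cv$direction, estimator = result$cv$estimator,
    r_attended = result$cv$r_attended, r_unattended = result$cv$r_unattended,
    folds = result$cv$folds$assignment,
    per_fold = lapply(result$cv$fold_results, function(fr) {
      list(test_fold = fr$test_fold, lambda = fr$lambda,
           r_attended = fr$r_attended, r_unattended = fr$r_unattended,
           validation_curve = fr$mean_curve, lambdas = fr$lambdas)
    }))
  jsonlite::write_json(cv_report, file.path(outdir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA)
  all_dec <- do.call(rbind, lapply(names(result$decisions), function(sl) {
    cbind(segment_length_s = as.numeric(sl), result$decisions[[sl]])
  }))
  utils::write.table(all_dec, file.path(outdir, "decisions.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$accuracy, file.path(outdir, "accuracy.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(result$itr, file.path(outdir, "itr.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(result$roc), file.path(outdir, "roc.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(outdir)
}

#' Summarize and compare estimator runs
#'
#' Descriptive comparison table over experiments that share the same data
#' and fold assignment (a paired design); refuses mismatched folds.  Means
#' of correlations pass through the Fisher z-transform and accuracies
#' through the arcsine transform before averaging, then map back.
#'
#' @param bundles List of `trf_experiment` objects.
#' @return Data.frame: one row per estimator x segment length with
#'   `r_attended`, `accuracy`, `wolpaw_bits_min`, `nykopp_bits_min`.
#' @export
compare_estimators <- function(bundles) {
  stopifnot(length(bundles) >= 1L)
  ref <- bundles[[1]]
  rows <- list()
  for (b in bundles) {
    if (!identical(b$cv$folds$assignment, ref$cv$folds$assignment) ||
        !identical(b$dataset_fingerprint$labels, ref$dataset_fingerprint$labels)) {
      stop_invalid("experiments do not share data and fold assignment; ",
                   "refusing an unpaired comparison")
    }
    per_fold_r <- vapply(b$cv$fold_results, `[[`, numeric(1), "r_attended")
    for (k in seq_len(nrow(b$accuracy))) {
      sl <- b$accuracy$segment_length_s[k]
      dec <- b$decisions[[as.character(sl)]]
      acc_by_fold <- vapply(split(dec$predicted == dec$label, dec$fold),
                            mean, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = if (b$config$estimator == "elasticnet")
          sprintf("elasticnet(a=%g)", b$config$alpha) else b$config$estimator,
        direction = b$config$direction,
        segment_length_s = sl,
        r_attended = fisher_mean(per_fold_r),
        r_attended_sd = stats::sd(per_fold_r),
        accuracy = arcsine_inv(mean(arcsine(acc_by_fold))),
        accuracy_sd = stats::sd(acc_by_fold),
        wolpaw_bits_min = b$itr$wolpaw_bits_min[k],
        nykopp_bits_min = b$itr$nykopp_bits_min[k])
    }
  }
  do.call(rbind, rows)
}
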