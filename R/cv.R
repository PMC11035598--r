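#' Subject-partitioned fold assignment
#'
#' Shuffles participants with the trial seed and splits them into `k`
#' near-equal folds, so all of a participant's samples share a fold.
#'
#' @param participants Character vector of participant ids.
#' @param k Number of folds.
#' @param seed Trial seed.
#' @return Named integer vector: fold (1..k) per participant.
#' @export
make_subject_folds <- function(participants, k = 5, seed = 1L) {
  participants <- unique(participants)
  n <- length(participants)
  if (k > n) stop_config("k = %d folds but only %d participants", k, n)
  ord <- with_seed(seed, sample.int(n))
  setNames(rep_len(seq_len(k), n)[order(ord)], participants)
}

#' Repeated subject-partitioned cross-validation
#'
#' Runs `n_trials` independent 5-fold cross-validation trials. In each
#' trial participants are reshuffled into folds; per fold, the feature
#' preprocessing pipeline and the model are fitted on the other folds
#' only and applied to the held-out fold, and out-of-fold predictions are
#' concatenated to give one risk per sample per trial. Per-trial overall
#' AUC is summarized as the median and 2.5/97.5 percentiles across
#' trials.
#'
#' @param features Raw (unpreprocessed) feature table keyed by
#'   `participant_id`, `reporting_week`.
#' @param labels Sample labels from [build_labels()] (after
#'   [completeness_filter()]).
#' @param spec A [model_spec()]; default [default_model_spec()].
#' @param n_trials Number of shuffled trials.
#' @param k Folds per trial.
#' @param seed Master seed; trial t uses a seed derived from `(seed, t)`.
#' @return A `cv_result`: list with `predictions` (trial, fold,
#'   participant_id, reporting_week, risk, label), `trial_auc`, and
#'   `summary` (median and percentile CI of the overall AUC).
#' @export
run_cv_trials <- function(features, labels, spec = default_model_spec(),
                          n_trials = 100, k = 5, seed = 1L) {
  feat <- data.table::as.data.table(features)
  lab <- data.table::as.data.table(labels)
  dat <- merge(feat, lab[, c("participant_id", "reporting_week", "csd"),
                         with = FALSE],
               by = c("participant_id", "reporting_week"))
  if (nrow(dat) != nrow(lab))
    stop_config("features and labels do not join one-to-one (%d vs %d rows)",
                nrow(dat), nrow(lab))
  id_cols <- c("participant_id", "reporting_week")
  fcols <- setdiff(names(feat), id_cols)
  feat_dat <- dat[, c(id_cols, fcols), with = FALSE]
  participants <- unique(dat$participant_id)
  preds <- vector("list", n_trials)
  trial_auc <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    folds <- make_subject_folds(participants, k,
                                derive_seed(seed, "folds", tr))
    fold_of <- folds[dat$participant_id]
    out <- vector("list", k)
    for (f in seq_len(k)) {
      test <- fold_of == f
      if (length(unique(dat$csd[!test])) < 2)
        stop_config("trial %d aborted: single-class training fold %d", tr, f)
      pp <- preprocess_features(feat_dat, !test)
      m <- train_risk_model(spec, pp$x[!test, , drop = FALSE],
                            dat$csd[!test],
                            derive_seed(seed, "model", tr, f))
      risk <- predict_risk(m, pp$x[test, , drop = FALSE])
      out[[f]] <- data.table::data.table(
        trial = tr, fold = f,
        participant_id = dat$participant_id[test],
        reporting_week = dat$reporting_week[test],
        risk = risk, label = dat$csd[test])
    }
    ptr <- data.table::rbindlist(out)
    preds[[tr]] <- ptr
    trial_auc[tr] <- pairwise_auc(ptr$risk[ptr$label], ptr$risk[!ptr$label])
  }
  predictions <- data.table::rbindlist(preds)
  structure(list(
    predictions = predictions,
    trial_auc = trial_auc,
    summary = c(median = median(trial_auc),
                ci_low = unname(quantile(trial_auc, 0.025)),
                ci_high = unname(quantile(trial_auc, 0.975))),
    spec = spec, n_trials = n_trials, k = k, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d trials x %d folds, %d predictions\n",
              x$n_trials, x$k, nrow(x$predictions)))
  cat(sprintf("  overall AUC median %.3f (95%% CI %.3f-%.3f)\n",
              x$summary["median"], x$summary["ci_low"],
              x$summary["ci_high"]))
  invisible(x)
}

#' Naive carry-forward baseline
#'
#' Re-predicts each participant's first reporting-week mean PHQ-8 (scaled
#' to `[0, 1]` by dividing by 24) as the risk for all later reporting
#' weeks. First-week samples are excluded from evaluation. Any monotone
#' rescaling yields the same ranking metrics.
#'
#' @param labels Filtered labels ([completeness_filter()] output).
#' @param schedule Reporting-week schedule; the first element is the
#'   anchor week.
#' @return data.table shaped like `cv_result$predictions` (single trial).
#' @export
naive_baseline <- function(labels, schedule) {
  lab <- data.table::as.data.table(labels)
  first_week <- min(schedule)
  base <- lab[lab$reporting_week == first_week,
              c("participant_id", "mean_total"), with = FALSE]
  data.table::setnames(base, "mean_total", "first_total")
  later <- merge(lab[lab$reporting_week != first_week], base,
                 by = "participant_id")
  data.table::data.table(
    trial = 1L, fold = NA_integer_,
    participant_id = later$participant_id,
    reporting_week = later$reporting_week,
    risk = later$first_total / 24,
    label = later$csd)
}
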