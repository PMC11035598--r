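#' Tie-aware pairwise AUC
#'
#' The probability that a randomly drawn positive risk ranks above a
#' randomly drawn negative risk, with ties counted as half:
#' `(#(pos > neg) + 0.5 #(pos = neg)) / (n_pos * n_neg)`. Computed via the
#' rank-sum (Mann-Whitney) identity with midranks, which is exactly the
#' half-credit tie rule.
#'
#' @param pos Risks of positive (CSD) samples.
#' @param neg Risks of negative (RH) samples.
#' @return AUC in `[0, 1]`, or `NA` when either side is empty.
#' @export
pairwise_auc <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Ranking-bias metrics per subgroup, per trial
#'
#' For each attribute, each subgroup with at least `min_participants`
#' participants among the predictions, and each trial, computes:
#' * `subgroup_auc` — subgroup CSD vs subgroup RH samples;
#' * `bnsp_auc` — subgroup CSD vs RH samples from all *other* subgroups of
#'   the attribute (the background);
#' * `bpsn_auc` — background CSD vs subgroup RH samples.
#'
#' Subgroups labeled `"Don't know"` / `"Prefer not to answer"` are not
#' reported but still contribute to the background.
#'
#' @param predictions Prediction records (`trial`, `participant_id`,
#'   `reporting_week`, `risk`, `label`), e.g. `cv_result$predictions`.
#' @param attributes Attribute table (`participant_id` + one column per
#'   attribute).
#' @param min_participants Minimum subgroup size (participants).
#' @param exclude_subgroups Subgroup labels reported as `NA` rows
#'   (excluded) but retained in backgrounds.
#' @return data.table of `BiasRecord`s: attribute, subgroup, metric,
#'   trial, value, n_pos, n_neg.
#' @export
bias_metrics <- function(predictions, attributes, min_participants = 15,
                         exclude_subgroups = c("Don't know",
                                               "Prefer not to answer")) {
  preds <- data.table::as.data.table(predictions)
  attrs <- as.data.frame(attributes)
  attr_names <- setdiff(names(attrs), "participant_id")
  out <- list()
  for (a in attr_names) {
    sub_of <- setNames(attrs[[a]], attrs$participant_id)
    pa <- preds
    pa$subgroup <- sub_of[pa$participant_id]
    sizes <- tapply(attrs$participant_id, attrs[[a]],
                    function(x) length(unique(x)))
    sizes <- sizes[names(sizes) %in% unique(pa$subgroup)]
    report <- names(sizes)[sizes >= min_participants &
                             !(names(sizes) %in% exclude_subgroups)]
    skipped <- setdiff(names(sizes),
                       union(report, exclude_subgroups))
    if (length(skipped))
      message(sprintf("bias_metrics: '%s' subgroup(s) below %d participants excluded: %s",
                      a, min_participants, paste(skipped, collapse = ", ")))
    for (tr in unique(pa$trial)) {
      pt <- pa[pa$trial == tr]
      for (g in report) {
        ing <- pt$subgroup == g
        sp <- pt$risk[ing & pt$label]
        sn <- pt$risk[ing & !pt$label]
        bp <- pt$risk[!ing & pt$label]
        bn <- pt$risk[!ing & !pt$label]
        out[[length(out) + 1]] <- data.table::data.table(
          attribute = a, subgroup = g,
          metric = c("subgroup_auc", "bnsp_auc", "bpsn_auc"),
          trial = tr,
          value = c(pairwise_auc(sp, sn), pairwise_auc(sp, bn),
                    pairwise_auc(bp, sn)),
          n_pos = c(length(sp), length(sp), length(bp)),
          n_neg = c(length(sn), length(bn), length(sn)))
      }
    }
  }
  data.table::rbindlist(out)
}

#' Summarize bias records across trials
#'
#' Per (attribute, subgroup, metric): the median and 2.5/97.5 percentile
#' CI of the metric across trials, together with a per-attribute reference
#' distribution built per trial from the *median* subgroup value when the
#' attribute has more than two reported subgroups, otherwise the *maximum*
#' (highest-performing) subgroup value. The subgroup base rate (fraction
#' of its samples labeled CSD) is attached when predictions are supplied.
#'
#' @param records Output of [bias_metrics()].
#' @param predictions Optional prediction records used for base rates.
#' @param attributes Optional attribute table (needed with
#'   `predictions`).
#' @return data.table of `BiasSummary` rows.
#' @export
summarize_trials <- function(records, predictions = NULL,
                             attributes = NULL) {
  rec <- data.table::as.data.table(records)
  out <- list()
  for (a in unique(rec$attribute)) {
    ra <- rec[rec$attribute == a]
    groups <- unique(ra$subgroup)
    for (m in unique(ra$metric)) {
      rm_ <- ra[ra$metric == m]
      # per-trial reference: median subgroup (if >2 subgroups) else max
      wide <- data.table::dcast(rm_, trial ~ subgroup, value.var = "value")
      vals <- as.matrix(wide[, -1, drop = FALSE])
      ref <- if (length(groups) > 2) {
        apply(vals, 1, median, na.rm = TRUE)
      } else {
        apply(vals, 1, max, na.rm = TRUE)
      }
      for (g in groups) {
        v <- rm_$value[rm_$subgroup == g]
        out[[length(out) + 1]] <- data.table::data.table(
          attribute = a, subgroup = g, metric = m,
          median = median(v, na.rm = TRUE),
          ci_low = unname(quantile(v, 0.025, na.rm = TRUE)),
          ci_high = unname(quantile(v, 0.975, na.rm = TRUE)),
          ref_median = median(ref, na.rm = TRUE),
          ref_ci_low = unname(quantile(ref, 0.025, na.rm = TRUE)),
          ref_ci_high = unname(quantile(ref, 0.975, na.rm = TRUE)))
      }
    }
  }
  res <- data.table::rbindlist(out)
  if (!is.null(predictions) && !is.null(attributes)) {
    preds <- data.table::as.data.table(predictions)
    attrs <- as.data.frame(attributes)
    res$base_rate <- NA_real_
    for (i in seq_len(nrow(res))) {
      ids <- attrs$participant_id[attrs[[res$attribute[i]]] == res$subgroup[i]]
      sel <- preds$participant_id %in% ids
      if (any(sel)) res$base_rate[i] <- mean(preds$label[sel])
    }
  }
  res
}
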