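#' Score raw PHQ-8 item responses
#'
#' Validates the 8 item scores (integers in 0..3) and computes the summed
#' total (0..24). Totals of 10 or more indicate clinically-significant
#' depression (CSD).
#'
#' @param raw Data frame with columns `participant_id`, `t` (seconds from
#'   study start) and `item1`..`item8`.
#' @return The input with a `total` column, as a data.table.
#' @export
score_phq8 <- function(raw) {
  items <- as.matrix(raw[, paste0("item", 1:8)])
  bad <- which(items != round(items) | items < 0 | items > 3, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_config("PHQ-8 item out of range 0..3 at row %d (item%d)",
                bad[1, 1], bad[1, 2])
  }
  out <- data.table::as.data.table(raw)
  out$total <- as.integer(rowSums(items))
  out
}

#' Build reporting-week sample labels
#'
#' PHQ-8 totals are averaged within each scheduled reporting week ("week
#' w" covers days `[7(w-1), 7w)` from study start) and binarized at the
#' clinical threshold: CSD when the week's mean total is >= 10, relatively
#' healthy (RH) otherwise. Responses outside any scheduled week are
#' ignored with a message.
#'
#' @param responses Scored responses (see [score_phq8()]): columns
#'   `participant_id`, `t`, `total`.
#' @param schedule Integer vector of reporting weeks, e.g.
#'   [reporting_weeks()] output.
#' @return data.table: participant_id, reporting_week, mean_total, csd.
#' @export
build_labels <- function(responses, schedule) {
  dt <- data.table::as.data.table(responses)
  dt$reporting_week <- floor(dt$t / (7 * SECONDS_PER_DAY)) + 1L
  off <- !(dt$reporting_week %in% schedule)
  if (any(off)) {
    message(sprintf("build_labels: ignoring %d responses outside scheduled reporting weeks",
                    sum(off)))
    dt <- dt[!off]
  }
  mean_total <- reporting_week <- participant_id <- NULL  # NSE guards
  lab <- dt[, list(mean_total = mean(total)),
            by = list(participant_id, reporting_week)]
  lab$csd <- lab$mean_total >= 10
  data.table::setorder(lab, participant_id, reporting_week)
  lab[]
}

#' Completeness filter: retain participants with every reporting week
#'
#' Keeps only participants who contributed at least one PHQ-8 response in
#' each scheduled reporting week; all other participants are dropped
#' entirely, so every retained participant contributes exactly
#' `length(schedule)` samples.
#'
#' @param labels Output of [build_labels()].
#' @param schedule Integer vector of scheduled reporting weeks.
#' @return The filtered labels, with retained participant ids in
#'   `attr(, "retained")`.
#' @export
completeness_filter <- function(labels, schedule) {
  dt <- data.table::as.data.table(labels)
  participant_id <- reporting_week <- NULL
  cov <- dt[reporting_week %in% schedule,
            list(n_weeks = length(unique(reporting_week))),
            by = participant_id]
  keep <- cov$participant_id[cov$n_weeks == length(schedule)]
  out <- dt[participant_id %in% keep & reporting_week %in% schedule]
  data.table::setorder(out, participant_id, reporting_week)
  attr(out, "retained") <- sort(keep)
  out
}
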