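#' Names of all sensed-behavior features
#'
#' @return Character vector: 7 location + 25 phone + 3 sleep features.
#' @export
sensed_feature_names <- function() {
  c("loc_variance", "loc_unique_locations", "loc_entropy",
    "loc_entropy_norm", "loc_home_frac", "loc_pct_transition",
    "loc_circadian_movement",
    phone_feature_names(),
    "sleep_onset_avg", "sleep_duration_avg", "sleep_duration_std")
}

#' Sensed-behavior features for one participant-window
#'
#' @param gps GPS fixes for one participant (`t`, `lat`, `lon`).
#' @param screen Screen events for one participant (`t`, `event`).
#' @param window Half-open `[start, end)` window in seconds from study
#'   start; clipped below at 0 (no data exists before the study begins).
#' @param min_gps_frac Minimum fraction of cadence-implied GPS fixes that
#'   must be present for the location family to be computed; otherwise the
#'   location features are missing.
#' @return Named numeric vector over [sensed_feature_names()].
#' @export
feature_window <- function(gps, screen, window, min_gps_frac = 0.5) {
  window[1] <- max(window[1], 0)
  g <- gps[gps$t >= window[1] & gps$t < window[2], , drop = FALSE]
  s <- screen[screen$t >= window[1] & screen$t < window[2], , drop = FALSE]
  expected <- (window[2] - window[1]) / GPS_CADENCE_S
  loc <- if (nrow(g) >= max(2, min_gps_frac * expected)) {
    compute_location_features(g, cluster_locations(g))
  } else {
    compute_location_features(g[0, ], NULL)
  }
  c(loc, compute_phone_features(s, window), infer_sleep(s, window))
}

#' Extract sensed-behavior features aligned to reporting weeks
#'
#' Computes, for every participant and scheduled reporting week, the full
#' feature vector over the 14 days ending with that reporting week
#' (days `[7w - 14, 7w)` from study start, clipped at the study start for
#' week 1).
#'
#' @param cohort A `sense_cohort`, or a list with `gps`, `screen` and
#'   either `config` or an explicit `schedule`.
#' @param schedule Optional integer vector of reporting weeks (defaults to
#'   the cohort config's schedule).
#' @param participants Optional participant ids (defaults to everyone with
#'   any stream data).
#' @param min_gps_frac See [feature_window()].
#' @return data.table: participant_id, reporting_week, one column per
#'   feature.
#' @export
compute_features <- function(cohort, schedule = NULL, participants = NULL,
                             min_gps_frac = 0.5) {
  gps <- data.table::as.data.table(cohort$gps)
  screen <- data.table::as.data.table(cohort$screen)
  if (is.null(schedule)) schedule <- reporting_weeks(cohort$config)
  if (is.null(participants)) {
    participants <- sort(unique(c(gps$participant_id, screen$participant_id)))
  }
  data.table::setkey(gps, participant_id)
  data.table::setkey(screen, participant_id)
  fn <- sensed_feature_names()
  rows <- vector("list", length(participants) * length(schedule))
  r <- 0L
  for (pid in participants) {
    g <- gps[data.table::J(pid), nomatch = NULL]
    s <- screen[data.table::J(pid), nomatch = NULL]
    for (w in schedule) {
      win <- c((7 * w - 14) * SECONDS_PER_DAY, 7 * w * SECONDS_PER_DAY)
      f <- feature_window(g, s, win, min_gps_frac)
      r <- r + 1L
      rows[[r]] <- c(list(participant_id = pid, reporting_week = w),
                     as.list(f[fn]))
    }
  }
  data.table::rbindlist(rows)
}
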