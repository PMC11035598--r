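PHONE_EPOCHS <- c(night = 0L, morning = 1L, afternoon = 2L, evening = 3L)
# night = 12-6 AM, morning = 6-12 (the "6-12 PM" epoch), afternoon = 12-6 PM,
# evening = 6-12 AM

phone_feature_names <- function() {
  ep <- names(PHONE_EPOCHS)
  per_epoch <- unlist(lapply(ep, function(e)
    paste0("phone_", c("dur", "dur", "unlock", "unlock"), "_", e,
           c("_avg", "_std", "_avg", "_std"))))
  c("phone_dur_daily_avg", "phone_dur_daily_std",
    "phone_unlock_daily_avg", "phone_unlock_daily_std",
    per_epoch, paste0("phone_days_use_", ep), "phone_days_use_total")
}

# population SD (divisor n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Derive screen sessions (on -> next off) from an event stream; unmatched
# "on" events are capped at 10 min or the next "on", whichever comes first.
screen_sessions <- function(events, cap_s = 600) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  ev <- events[order(events$t), ]
  on_t <- ev$t[ev$event == "on"]
  off_t <- sort(ev$t[ev$event == "off"])
  if (!length(on_t)) return(data.frame(start = numeric(0), end = numeric(0)))
  j <- findInterval(on_t, off_t) + 1
  off_next <- ifelse(j <= length(off_t), off_t[pmin(j, length(off_t))], Inf)
  nxt_on <- c(on_t[-1], Inf)
  # a matched off (before the next on) ends the session; otherwise fall
  # back to the cap or the next unlock, whichever comes first
  end <- ifelse(off_next <= nxt_on, off_next, pmin(nxt_on, on_t + cap_s))
  keep <- end > on_t & is.finite(end)
  data.frame(start = on_t[keep], end = end[keep])
}

#' Phone-usage feature family over one window
#'
#' Derives screen sessions from on/off events and summarizes usage over
#' every day of the window: average and (population) standard deviation of
#' daily usage duration (minutes) and daily unlock counts, the same per
#' 6-hour epoch (12-6 AM, 6-12, 12-6 PM, 6-12 AM; session time is
#' apportioned to days and epochs by overlap, unlocks count where the
#' session starts), and the number of days with any use per epoch and
#' overall. Days without events count as zeros; a window with no events at
#' all yields all-zero features, since absence of phone use is itself
#' informative.
#'
#' @param events Screen events in or around the window (`t`, `event`).
#' @param window Numeric `c(start, end)` in seconds from study start; the
#'   window is half-open `[start, end)` and must span whole days.
#' @return Named numeric vector of the 25 phone features.
#' @export
compute_phone_features <- function(events, window) {
  n_days <- round((window[2] - window[1]) / SECONDS_PER_DAY)
  dur <- matrix(0, n_days, 4)
  unl <- matrix(0L, n_days, 4)
  ses <- screen_sessions(events)
  ses$start <- pmax(ses$start, window[1])
  ses$end <- pmin(ses$end, window[2])
  ses <- ses[ses$end > ses$start, , drop = FALSE]
  if (nrow(ses)) {
    # apportion session time to 6h slots by overlap
    s0 <- floor((ses$start - window[1]) / 21600)
    s1 <- ceiling((ses$end - window[1]) / 21600) - 1
    reps <- s1 - s0 + 1
    slot <- unlist(mapply(seq, s0, s1, SIMPLIFY = FALSE))
    sidx <- rep(seq_len(nrow(ses)), reps)
    lo <- pmax(ses$start[sidx] - window[1], slot * 21600)
    hi <- pmin(ses$end[sidx] - window[1], (slot + 1) * 21600)
    day <- slot %/% 4 + 1
    ep <- slot %% 4 + 1
    for (i in seq_along(slot)) dur[day[i], ep[i]] <- dur[day[i], ep[i]] + (hi[i] - lo[i])
    st_slot <- floor((ses$start - window[1]) / 21600)
    sd_day <- st_slot %/% 4 + 1
    sd_ep <- st_slot %% 4 + 1
    for (i in seq_len(nrow(ses))) unl[sd_day[i], sd_ep[i]] <- unl[sd_day[i], sd_ep[i]] + 1L
  }
  dur <- dur / 60  # minutes
  daily_dur <- rowSums(dur)
  daily_unl <- rowSums(unl)
  feat <- c(phone_dur_daily_avg = mean(daily_dur),
            phone_dur_daily_std = sd_pop(daily_dur),
            phone_unlock_daily_avg = mean(daily_unl),
            phone_unlock_daily_std = sd_pop(daily_unl))
  for (e in seq_along(PHONE_EPOCHS)) {
    nm <- names(PHONE_EPOCHS)[e]
    feat[paste0("phone_dur_", nm, "_avg")] <- mean(dur[, e])
    feat[paste0("phone_dur_", nm, "_std")] <- sd_pop(dur[, e])
    feat[paste0("phone_unlock_", nm, "_avg")] <- mean(unl[, e])
    feat[paste0("phone_unlock_", nm, "_std")] <- sd_pop(unl[, e])
  }
  for (e in seq_along(PHONE_EPOCHS)) {
    feat[paste0("phone_days_use_", names(PHONE_EPOCHS)[e])] <- sum(dur[, e] > 0)
  }
  feat["phone_days_use_total"] <- sum(daily_dur > 0)
  feat
}

#' Infer nightly sleep from screen-interaction gaps
#'
#' For each night of the window, sleep is taken as the longest gap between
#' consecutive phone interactions (any screen event) starting between
#' 20:00 and noon the next day, with duration between 3 and 14 hours.
#' Nights without such a gap are excluded; all three features are missing
#' when fewer than `min_nights` nights are valid. Onset is the circular
#' mean of gap-start clock times (hours, 24 h circle); duration statistics
#' use the population SD.
#'
#' @param events Screen events (`t`, `event`).
#' @param window Numeric `c(start, end)` window in seconds (whole days).
#' @param min_nights Minimum valid nights for non-missing output.
#' @return Named numeric vector: `sleep_onset_avg` (clock hours in
#'   `[0, 24)`), `sleep_duration_avg`, `sleep_duration_std` (hours).
#' @export
infer_sleep <- function(events, window, min_nights = 7) {
  n_days <- round((window[2] - window[1]) / SECONDS_PER_DAY)
  onsets <- durations <- numeric(0)
  ts <- if (is.null(events) || nrow(events) == 0) numeric(0) else sort(events$t)
  for (d in seq_len(n_days) - 1) {
    span0 <- window[1] + d * SECONDS_PER_DAY + 20 * 3600
    span1 <- window[1] + (d + 1) * SECONDS_PER_DAY + 12 * 3600
    x <- ts[ts >= span0 & ts <= span1]
    if (length(x) < 2) next
    gaps <- diff(x)
    ok <- gaps >= 3 * 3600 & gaps <= 14 * 3600
    if (!any(ok)) next
    j <- which(ok)[which.max(gaps[ok])]
    onsets <- c(onsets, (x[j] %% SECONDS_PER_DAY) / 3600)
    durations <- c(durations, gaps[j] / 3600)
  }
  if (length(durations) < min_nights) {
    return(c(sleep_onset_avg = NA_real_, sleep_duration_avg = NA_real_,
             sleep_duration_std = NA_real_))
  }
  c(sleep_onset_avg = circular_mean_hours(onsets),
    sleep_duration_avg = mean(durations),
    sleep_duration_std = sd_pop(durations))
}
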