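#' Sample participant profiles for a synthetic cohort
#'
#' Draws per-participant attribute labels (independently per attribute from
#' the configured marginals) and latent behavioral knobs: home and routine
#' place coordinates with daily visit templates, movement regularity,
#' per-epoch phone session rates and mean session length, habitual sleep
#' onset and duration, and a latent severity baseline. Subgroup shifts from
#' `config$knob_shifts` are applied additively in prior-SD units.
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `participant_profiles`, one row per
#'   participant, with attribute columns, knob columns, and a `places`
#'   list-column of routine-place coordinates and visit templates.
#' @export
sample_profiles <- function(config) {
  validate_cohort_config(config)
  n <- config$n_participants
  mom <- knob_prior_moments(config$behavior_knob_priors)
  rownames(mom) <- mom$knob
  with_seed(derive_seed(config$seed, "profiles"), {
    prof <- data.frame(
      participant_id = sprintf("P%04d", seq_len(n)),
      idx = seq_len(n),
      stringsAsFactors = FALSE
    )
    for (a in names(config$attribute_distributions)) {
      p <- config$attribute_distributions[[a]]
      prof[[a]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
    for (k in names(config$behavior_knob_priors)) {
      prior <- config$behavior_knob_priors[[k]]
      x <- draw_knob(prior, n)
      sh <- config$knob_shifts[config$knob_shifts$knob == k, , drop = FALSE]
      if (nrow(sh)) for (i in seq_len(nrow(sh))) {
        hit <- prof[[sh$attribute[i]]] == sh$subgroup[i]
        x[hit] <- x[hit] + sh$shift[i] * mom[k, "sd"]
      }
      prof[[k]] <- knob_support_clamp(k, x, prior)
    }
    prof$sleep_onset_h <- prof$sleep_onset_h %% 24
    # abstract geography: homes scattered ~10 km around the origin,
    # routine places 0.5-5 km from home with fixed daily visit templates
    prof$home_lat <- config$origin_lat + rnorm(n, 0, 0.05)
    prof$home_lon <- config$origin_lon + rnorm(n, 0, 0.05)
    places <- vector("list", n)
    for (i in seq_len(n)) {
      k <- prof$n_routine_places[i]
      d_km <- runif(k, 0.5, 5)
      ang <- runif(k, 0, 2 * pi)
      places[[i]] <- data.frame(
        lat = prof$home_lat[i] + d_km * sin(ang) / 111.32,
        lon = prof$home_lon[i] + d_km * cos(ang) /
          (111.32 * cos(prof$home_lat[i] * pi / 180)),
        visit_start_h = runif(k, 8, 18),
        visit_len_h = runif(k, 1, 3)
      )
    }
    prof$places <- I(places)
    prof$severity_baseline <- rnorm(n, 0, config$baseline_sd)
    class(prof) <- c("participant_profiles", "data.frame")
    prof
  })
}

#' Generate raw GPS and screen-event streams for participants
#'
#' GPS fixes are produced on the nominal 5-minute grid for the whole
#' protocol: participants dwell at their home and routine places (positions
#' jittered by `dwell_jitter_m`), travel between places along straight-line
#' transitions at `transit_speed_kmh`, and follow their daily visit
#' template with probability equal to the movement-regularity knob (other
#' days get a shuffled schedule). Screen sessions arrive per 6-hour epoch
#' at the participant's session rates, are suppressed and truncated inside
#' the habitual sleep window, and are emitted as alternating on/off events.
#' Stream-level missingness is applied last.
#'
#' @param profiles One or more rows of [sample_profiles()] output.
#' @param config The same [cohort_config()].
#' @return List with `gps` (participant_id, t, lat, lon) and `screen`
#'   (participant_id, t, event) data.tables; `t` is seconds from study
#'   start.
#' @export
generate_streams <- function(profiles, config) {
  gps_l <- vector("list", nrow(profiles))
  scr_l <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    res <- with_seed(derive_seed(config$seed, "streams", p$idx),
                     generate_streams_one(p, config))
    gps_l[[i]] <- res$gps
    scr_l[[i]] <- res$screen
  }
  list(gps = data.table::rbindlist(gps_l),
       screen = data.table::rbindlist(scr_l))
}

generate_streams_one <- function(p, config) {
  n_days <- config$study_weeks * 7
  nslot <- SECONDS_PER_DAY / GPS_CADENCE_S  # 288
  places <- rbind(
    data.frame(lat = p$home_lat, lon = p$home_lon,
               visit_start_h = NA, visit_len_h = NA),
    p$places[[1]]
  )
  n_total <- n_days * nslot
  slot_place <- rep(1L, n_total)  # place 1 = home
  slot_h <- (seq_len(nslot) - 1) * GPS_CADENCE_S / 3600
  regular <- runif(n_days) < p$movement_regularity
  k_routine <- nrow(places) - 1
  for (d in seq_len(n_days)) {
    off <- (d - 1) * nslot
    for (j in seq_len(k_routine)) {
      st <- places$visit_start_h[j + 1]
      len <- places$visit_len_h[j + 1]
      if (!regular[d]) st <- runif(1, 8, 18)
      sel <- slot_h >= st & slot_h < st + len
      slot_place[off + which(sel)] <- j + 1L
    }
  }
  # sleep window forces home
  t_slot <- (seq_len(n_total) - 1) * GPS_CADENCE_S
  # include a "day -1" window so the first morning's spillover is covered
  sleep_start <- ((-1):(n_days - 1)) * SECONDS_PER_DAY +
    p$sleep_onset_h * 3600
  sleep_end <- sleep_start + p$sleep_dur_h * 3600
  iv <- findInterval(t_slot, sleep_start)
  asleep <- iv >= 1 & t_slot < sleep_end[pmax(iv, 1)]
  slot_place[asleep] <- 1L
  lat <- places$lat[slot_place]
  lon <- places$lon[slot_place]
  in_transit <- rep(FALSE, n_total)
  # straight-line transitions at the configured speed whenever the
  # dwell place changes between consecutive runs
  r <- rle(slot_place)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  if (length(r$values) > 1) {
    for (k in 2:length(r$values)) {
      from <- r$values[k - 1]; to <- r$values[k]
      if (from == to) next
      d_m <- haversine_m(places$lat[from], places$lon[from],
                         places$lat[to], places$lon[to])
      tt_s <- d_m / (config$transit_speed_kmh / 3.6)
      ntr <- min(ceiling(tt_s / GPS_CADENCE_S), r$lengths[k])
      if (ntr < 1) next
      idx <- starts[k] + seq_len(ntr) - 1
      f <- pmin(seq_len(ntr) * GPS_CADENCE_S / tt_s, 1)
      lat[idx] <- places$lat[from] + f * (places$lat[to] - places$lat[from])
      lon[idx] <- places$lon[from] + f * (places$lon[to] - places$lon[from])
      in_transit[idx] <- f < 1
    }
  }
  jit <- config$dwell_jitter_m
  lat <- lat + rnorm(n_total, 0, jit / 111320)
  lon <- lon + rnorm(n_total, 0, jit / (111320 * cos(p$home_lat * pi / 180)))
  keep <- runif(n_total) >= config$missingness$gps_drop
  gps <- data.table::data.table(participant_id = p$participant_id,
                                t = t_slot[keep], lat = lat[keep],
                                lon = lon[keep])

  # screen sessions: Poisson counts per day x epoch, exponential lengths
  rates <- c(p$session_rate_night, p$session_rate_morning,
             p$session_rate_afternoon, p$session_rate_evening)
  counts <- rpois(n_days * 4, rep(rates, times = n_days))
  day_of <- rep(rep(seq_len(n_days) - 1, each = 4), counts)
  epoch_of <- rep(rep(0:3, times = n_days), counts)
  ns <- length(day_of)
  if (ns > 0) {
    start <- day_of * SECONDS_PER_DAY + (epoch_of * 6 + runif(ns) * 6) * 3600
    dur <- pmax(rexp(ns, rate = 1 / (p$session_mean_min * 60)), 5)
    dur <- pmin(dur, 3 * 3600)
    end <- start + dur
    # suppress sessions starting inside the sleep window; truncate ends
    # at the next sleep onset
    iv <- findInterval(start, sleep_start)
    in_sleep <- iv >= 1 & start < sleep_end[pmax(iv, 1)]
    nxt <- c(sleep_start, Inf)[pmin(iv + 1, length(sleep_start) + 1)]
    end <- pmin(end, nxt)
    ok <- !in_sleep & end > start
    start <- start[ok]; end <- end[ok]
    ord <- order(start)
    start <- start[ord]; end <- end[ord]
    # drop overlapping sessions so on/off events alternate cleanly
    if (length(start) > 1) {
      keep <- rep(TRUE, length(start))
      prev_end <- end[1]
      for (s in 2:length(start)) {
        if (start[s] < prev_end) keep[s] <- FALSE
        else prev_end <- end[s]
      }
      start <- start[keep]; end <- end[keep]
    }
    keep <- runif(length(start)) >= config$missingness$screen_drop
    start <- start[keep]; end <- end[keep]
  } else {
    start <- end <- numeric(0)
  }
  screen <- data.table::data.table(
    participant_id = p$participant_id,
    t = c(rbind(start, end)),
    event = rep(c("on", "off"), times = length(start))
  )
  list(gps = gps, screen = screen)
}

#' Generate PHQ-8 responses with planted subgroup-specific couplings
#'
#' Latent week severity is `intercept + baseline + sum over configured
#' couplings of coef * standardized knob + N(0, severity_noise_sd)`; each
#' of the `phq8_per_reporting_week` responses in the week adds
#' `N(0, response_noise_sd)`, is rounded and clipped to 0..24, and is
#' decomposed into 8 item scores (0..3) by largest-remainder rounding of
#' the configured item weights. The intercept is calibrated so the pooled
#' fraction of weeks with mean total >= 10 matches `target_base_rate`
#' (see [calibrate_config()]). Whole reporting weeks are dropped with
#' probability `missingness$week_miss`.
#'
#' @param profiles Rows of [sample_profiles()] output.
#' @param config The same [cohort_config()].
#' @return data.table: participant_id, t, item1..item8, total.
#' @export
generate_outcomes <- function(profiles, config) {
  config <- calibrate_config(config)
  mom <- config$calibration$knob_moments
  rownames(mom) <- mom$knob
  weeks <- reporting_weeks(config)
  cc <- config$outcome_coefficients
  J <- config$phq8_per_reporting_week
  out <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    lin <- 0
    if (nrow(cc)) for (r in seq_len(nrow(cc))) {
      if (p[[cc$attribute[r]]] == cc$subgroup[r]) {
        z <- (p[[cc$knob[r]]] - mom[cc$knob[r], "mean"]) / mom[cc$knob[r], "sd"]
        lin <- lin + cc$coef[r] * z
      }
    }
    mu <- config$calibration$intercept + p$severity_baseline + lin
    out[[i]] <- with_seed(derive_seed(config$seed, "outcomes", p$idx), {
      t_all <- numeric(0); tot_all <- integer(0)
      for (wi in seq_along(weeks)) {
        if (runif(1) < config$missingness$week_miss) next
        sev <- mu + rnorm(1, 0, config$severity_noise_sd)
        tt <- (weeks[wi] - 1) * 7 * SECONDS_PER_DAY +
          sort(runif(J, 0, 7)) * SECONDS_PER_DAY
        tot <- as.integer(clamp(round(sev + rnorm(J, 0, config$response_noise_sd)),
                                0, 24))
        t_all <- c(t_all, tt); tot_all <- c(tot_all, tot)
      }
      if (!length(t_all)) return(NULL)
      items <- t(vapply(tot_all, largest_remainder_alloc, integer(8),
                        weights = config$item_weights, cap = 3L))
      colnames(items) <- paste0("item", 1:8)
      data.table::data.table(participant_id = p$participant_id,
                             t = t_all, items, total = tot_all)
    })
  }
  data.table::rbindlist(out)
}

#' Assemble a complete synthetic cohort
#'
#' Runs [sample_profiles()], [generate_streams()] and
#' [generate_outcomes()] under the config's master seed and bundles the
#' results with a manifest (seed, config hash, row counts). If `dir` is
#' given, writes the standard plain-text artifact files: `attributes.csv`,
#' `gps.csv`, `screen.csv`, `phq8.csv` (ISO timestamps) and
#' `manifest.json`.
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory.
#' @param streams If `FALSE`, skip the (comparatively large) sensor
#'   streams and generate attributes and PHQ-8 outcomes only — enough for
#'   label and schedule accounting.
#' @return An object of class `sense_cohort`: list with `config`,
#'   `profiles`, `attributes`, `gps`, `screen`, `phq8`, `manifest`.
#' @export
assemble_cohort <- function(config, dir = NULL, streams = TRUE) {
  config <- calibrate_config(config)
  profiles <- sample_profiles(config)
  attributes <- profiles[, c("participant_id",
                             names(config$attribute_distributions))]
  class(attributes) <- "data.frame"
  st <- if (streams) generate_streams(profiles, config)
        else list(gps = NULL, screen = NULL)
  phq8 <- generate_outcomes(profiles, config)
  manifest <- list(
    generator = "sensebias",
    seed = config$seed,
    config_hash = config_hash(config),
    n_participants = nrow(profiles),
    reporting_weeks = reporting_weeks(config),
    n_gps = if (streams) nrow(st$gps) else 0L,
    n_screen = if (streams) nrow(st$screen) else 0L,
    n_phq8 = nrow(phq8)
  )
  cohort <- structure(list(config = config, profiles = profiles,
                           attributes = attributes, gps = st$gps,
                           screen = st$screen, phq8 = phq8,
                           manifest = manifest),
                      class = "sense_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.sense_cohort <- function(x, ...) {
  cat(sprintf("<sense_cohort> %d participants, %d GPS fixes, %d screen events, %d PHQ-8 responses\n",
              x$manifest$n_participants, x$manifest$n_gps,
              x$manifest$n_screen, x$manifest$n_phq8))
  cat(sprintf("  seed %d, config %s\n", x$manifest$seed,
              x$manifest$config_hash))
  invisible(x)
}

# Stable hash of the scientific content of a config (calibration cache and
# class attributes excluded).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$calibration <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Write a cohort bundle to disk
#'
#' @param cohort A `sense_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ss <- cohort$config$study_start
  write.csv(cohort$attributes, file.path(dir, "attributes.csv"),
            row.names = FALSE)
  if (!is.null(cohort$gps)) {
    g <- data.frame(participant_id = cohort$gps$participant_id,
                    timestamp = iso_from_seconds(cohort$gps$t, ss),
                    lat = cohort$gps$lat, lon = cohort$gps$lon)
    write.csv(g, file.path(dir, "gps.csv"), row.names = FALSE)
    s <- data.frame(participant_id = cohort$screen$participant_id,
                    timestamp = iso_from_seconds(cohort$screen$t, ss),
                    event = cohort$screen$event)
    write.csv(s, file.path(dir, "screen.csv"), row.names = FALSE)
  }
  q <- data.frame(participant_id = cohort$phq8$participant_id,
                  timestamp = iso_from_seconds(cohort$phq8$t, ss))
  for (j in 1:8) q[[paste0("item", j)]] <- cohort$phq8[[paste0("item", j)]]
  write.csv(q, file.path(dir, "phq8.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(cohort$manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the artifact files.
#' @param study_start Study start date used to convert ISO timestamps back
#'   to seconds from study start.
#' @return A list with `attributes`, `gps`, `screen`, `phq8`, `manifest`
#'   in the in-memory (numeric time) representation.
#' @export
read_cohort <- function(dir, study_start = "2020-01-06") {
  attributes <- read.csv(file.path(dir, "attributes.csv"),
                         check.names = FALSE,
                         colClasses = "character")
  gps <- NULL
  screen <- NULL
  if (file.exists(file.path(dir, "gps.csv"))) {
    g <- data.table::fread(file.path(dir, "gps.csv"))
    gps <- data.table::data.table(
      participant_id = g$participant_id,
      t = seconds_from_iso(g$timestamp, study_start),
      lat = g$lat, lon = g$lon)
    s <- data.table::fread(file.path(dir, "screen.csv"))
    screen <- data.table::data.table(
      participant_id = s$participant_id,
      t = seconds_from_iso(s$timestamp, study_start),
      event = s$event)
  }
  q <- data.table::fread(file.path(dir, "phq8.csv"))
  phq8 <- data.table::data.table(
    participant_id = q$participant_id,
    t = seconds_from_iso(q$timestamp, study_start))
  for (j in 1:8) phq8[[paste0("item", j)]] <- q[[paste0("item", j)]]
  phq8$total <- as.integer(
    rowSums(as.matrix(phq8[, paste0("item", 1:8), with = FALSE])))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  list(attributes = attributes, gps = gps, screen = screen, phq8 = phq8,
       manifest = manifest)
}
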