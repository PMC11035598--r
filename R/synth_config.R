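#' Attribute marginals of the emulated study cohort
#'
#' Returns the per-attribute subgroup proportions used as the default
#' sampling marginals for synthetic cohorts: age band, sex at birth, race,
#' annual family income, health insurance status and employment status,
#' with the proportions observed in the 650-participant study cohort this
#' package emulates.
#'
#' @return Named list mapping attribute name to a named probability vector.
#' @export
study_attribute_marginals <- function() {
  lapply(list(
    age = c("18 to 25" = 60, "25 to 34" = 181, "35 to 44" = 168,
            "45 to 54" = 135, "55 to 64" = 81, "65 to 74" = 22,
            "75 to 84" = 3),
    sex = c(Female = 482, Male = 168),
    race = c(White = 534, "Black/African American" = 61,
             "Asian/Asian American" = 22, "More than one race" = 24,
             Other = 6, "Prefer not to answer" = 3),
    income = c("<20,000" = 98, "20,000 to 39,999" = 144,
               "40,000 to 59,999" = 124, "60,000 to 99,999" = 161,
               "100,000+" = 110, "Don't know" = 10,
               "Prefer not to answer" = 3),
    insurance = c(Insured = 603, Uninsured = 43, "Don't know" = 3,
                  "Prefer not to answer" = 1),
    employment = c(Employed = 401, Unemployed = 90, Disability = 72,
                   Retired = 34, Other = 52, "Prefer not to answer" = 1)
  ), function(x) x / sum(x))
}

default_knob_priors <- function() {
  list(
    n_routine_places    = list(dist = "categorical", values = 1:5,
                               probs = c(.15, .30, .30, .15, .10)),
    movement_regularity = list(dist = "beta", shape1 = 8, shape2 = 2),
    session_rate_night     = list(dist = "gamma", shape = 3, mean = 0.6),
    session_rate_morning   = list(dist = "gamma", shape = 5, mean = 5),
    session_rate_afternoon = list(dist = "gamma", shape = 5, mean = 6),
    session_rate_evening   = list(dist = "gamma", shape = 5, mean = 7),
    session_mean_min    = list(dist = "lnorm", meanlog = log(3), sdlog = 0.4),
    sleep_onset_h       = list(dist = "norm", mean = 23.5, sd = 1.0),
    sleep_dur_h         = list(dist = "norm", mean = 7.5, sd = 0.8)
  )
}

default_knob_shifts <- function() {
  data.frame(
    attribute = c("age", "age"),
    subgroup = c("18 to 25", "65 to 74"),
    knob = c("session_rate_morning", "session_rate_morning"),
    shift = c(0.32, -0.62),
    stringsAsFactors = FALSE
  )
}

default_outcome_coefficients <- function() {
  data.frame(
    attribute = c("age", "age", "employment", "employment"),
    subgroup = c("18 to 25", "65 to 74", "Employed", "Disability"),
    knob = c("session_rate_morning", "session_rate_morning",
             "movement_regularity", "movement_regularity"),
    coef = c(-2.0, 1.6, -0.5, 1.5),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic sensing cohort
#'
#' Assembles and validates the full description of a synthetic study:
#' the 16-week protocol with PHQ-8 reporting weeks every 3 weeks, 5-minute
#' GPS sampling, screen on/off sessions, attribute marginals, behavioral
#' knob priors (optionally shifted per subgroup), and signed
#' subgroup-specific couplings between knobs and latent depression
#' severity. The defaults emulate the cohort composition, ~46% base rate
#' of clinically-significant depression, and the sign-flipped
#' behavior-outcome couplings this package's audit is designed to expose.
#'
#' @param n_participants Number of participants to simulate.
#' @param study_weeks Protocol length in weeks.
#' @param reporting_start_week First PHQ-8 reporting week (1-based).
#' @param reporting_interval_weeks Weeks between reporting weeks.
#' @param phq8_per_reporting_week PHQ-8 prompts delivered per reporting week.
#' @param attribute_distributions Named list: attribute -> named probability
#'   vector over subgroups (must sum to 1 within 1e-9).
#' @param behavior_knob_priors Named list of prior specs for behavioral
#'   knobs (see [default_knob_priors()]).
#' @param knob_shifts Data frame (attribute, subgroup, knob, shift): additive
#'   subgroup shifts on knob values, in prior-SD units.
#' @param outcome_coefficients Data frame (attribute, subgroup, knob, coef):
#'   signed coupling between a prior-standardized knob and latent severity
#'   (PHQ-8 points per knob SD), applied only to members of the subgroup.
#' @param baseline_sd Between-participant SD of latent severity (points).
#' @param severity_noise_sd Week-level latent severity noise SD (points).
#' @param response_noise_sd Response-level noise SD around the week's
#'   severity (points).
#' @param target_base_rate Target pooled fraction of reporting weeks with
#'   mean PHQ-8 >= 10.
#' @param missingness List with `gps_drop`, `screen_drop` (per-record drop
#'   probabilities) and `week_miss` (probability a participant misses an
#'   entire reporting week).
#' @param seed Integer master seed; a fixed seed yields byte-identical
#'   cohorts.
#' @param origin_lat,origin_lon Abstract geographic origin of the cohort.
#' @param transit_speed_kmh Travel speed between routine places.
#' @param dwell_jitter_m GPS jitter SD (meters) while dwelling at a place.
#' @param item_weights Relative PHQ-8 item weights used to decompose totals
#'   into the 8 item scores.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 650,
                          study_weeks = 16,
                          reporting_start_week = 1,
                          reporting_interval_weeks = 3,
                          phq8_per_reporting_week = 3,
                          attribute_distributions = study_attribute_marginals(),
                          behavior_knob_priors = default_knob_priors(),
                          knob_shifts = default_knob_shifts(),
                          outcome_coefficients = default_outcome_coefficients(),
                          baseline_sd = 4,
                          severity_noise_sd = 2,
                          response_noise_sd = 1,
                          target_base_rate = 0.46,
                          missingness = list(gps_drop = 0.10,
                                             screen_drop = 0.05,
                                             week_miss = 0.06),
                          seed = 1L,
                          origin_lat = 40, origin_lon = -75,
                          transit_speed_kmh = 20,
                          dwell_jitter_m = 10,
                          item_weights = rep(1, 8)) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    study_weeks = as.integer(study_weeks),
    reporting_start_week = as.integer(reporting_start_week),
    reporting_interval_weeks = as.integer(reporting_interval_weeks),
    phq8_per_reporting_week = as.integer(phq8_per_reporting_week),
    attribute_distributions = attribute_distributions,
    behavior_knob_priors = behavior_knob_priors,
    knob_shifts = knob_shifts,
    outcome_coefficients = outcome_coefficients,
    baseline_sd = baseline_sd,
    severity_noise_sd = severity_noise_sd,
    response_noise_sd = response_noise_sd,
    target_base_rate = target_base_rate,
    missingness = missingness,
    seed = as.integer(seed),
    origin_lat = origin_lat, origin_lon = origin_lon,
    transit_speed_kmh = transit_speed_kmh,
    dwell_jitter_m = dwell_jitter_m,
    item_weights = item_weights,
    study_start = "2020-01-06"
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) stop_config("n_participants must be >= 1")
  for (a in names(cfg$attribute_distributions)) {
    p <- cfg$attribute_distributions[[a]]
    if (is.null(names(p)) || any(!nzchar(names(p))))
      stop_config("attribute '%s': subgroup probabilities must be named", a)
    if (any(p < 0 | p > 1))
      stop_config("attribute '%s': probabilities outside [0,1]", a)
    if (abs(sum(p) - 1) > 1e-9)
      stop_config("attribute '%s': probabilities sum to %.12f, not 1",
                  a, sum(p))
  }
  if (length(reporting_weeks(cfg)) < 1)
    stop_config("study schedule yields no reporting weeks")
  if (cfg$target_base_rate <= 0.02 || cfg$target_base_rate >= 0.98)
    stop_config("target_base_rate %.3f is outside the achievable range",
                cfg$target_base_rate)
  miss <- unlist(cfg$missingness)
  if (any(miss < 0 | miss >= 1))
    stop_config("missingness probabilities must be in [0, 1)")
  if (cfg$phq8_per_reporting_week < 1)
    stop_config("phq8_per_reporting_week must be >= 1")
  ok_knobs <- names(cfg$behavior_knob_priors)
  bad <- setdiff(unique(c(cfg$outcome_coefficients$knob,
                          cfg$knob_shifts$knob)), ok_knobs)
  if (length(bad))
    stop_config("unknown knob(s) in couplings/shifts: %s",
                paste(bad, collapse = ", "))
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d participants, %d weeks, reporting weeks {%s}\n",
              x$n_participants, x$study_weeks,
              paste(reporting_weeks(x), collapse = ", ")))
  cat(sprintf("  PHQ-8 per reporting week: %d; target CSD base rate: %.2f\n",
              x$phq8_per_reporting_week, x$target_base_rate))
  cat(sprintf("  attributes: %s\n",
              paste(names(x$attribute_distributions), collapse = ", ")))
  cat(sprintf("  planted couplings: %d; seed: %d\n",
              nrow(x$outcome_coefficients), x$seed))
  invisible(x)
}

#' Scheduled PHQ-8 reporting weeks
#'
#' @param config A `cohort_config`, or a list with `study_weeks`,
#'   `reporting_start_week` and `reporting_interval_weeks`.
#' @return Integer vector of reporting weeks (defaults: 1, 4, 7, 10, 13, 16).
#' @export
reporting_weeks <- function(config) {
  as.integer(seq.int(config$reporting_start_week, config$study_weeks,
                     by = config$reporting_interval_weeks))
}

# Analytic prior mean/sd per knob (used to standardize knobs for the
# severity model and to scale subgroup shifts).
knob_prior_moments <- function(priors) {
  out <- lapply(priors, function(p) {
    switch(p$dist,
      beta = {
        a <- p$shape1; b <- p$shape2
        m <- a / (a + b)
        v <- a * b / ((a + b)^2 * (a + b + 1))
        c(m, sqrt(v))
      },
      gamma = {
        sc <- p$mean / p$shape
        c(p$mean, sqrt(p$shape) * sc)
      },
      lnorm = {
        m <- exp(p$meanlog + p$sdlog^2 / 2)
        v <- (exp(p$sdlog^2) - 1) * m^2
        c(m, sqrt(v))
      },
      norm = c(p$mean, p$sd),
      categorical = {
        m <- sum(p$values * p$probs)
        v <- sum((p$values - m)^2 * p$probs)
        c(m, sqrt(v))
      },
      stop_config("unknown prior distribution '%s'", p$dist))
  })
  data.frame(knob = names(priors),
             mean = vapply(out, `[`, numeric(1), 1),
             sd = vapply(out, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}

# One random draw routine for knob priors (vectorized over n).
draw_knob <- function(p, n) {
  switch(p$dist,
    beta = rbeta(n, p$shape1, p$shape2),
    gamma = rgamma(n, shape = p$shape, scale = p$mean / p$shape),
    lnorm = rlnorm(n, p$meanlog, p$sdlog),
    norm = rnorm(n, p$mean, p$sd),
    categorical = p$values[sample.int(length(p$values), n, replace = TRUE,
                                      prob = p$probs)])
}

knob_support_clamp <- function(knob, x, prior) {
  switch(prior$dist,
    beta = clamp(x, 0, 1),
    gamma = pmax(x, 0.01),
    lnorm = pmax(x, 0.01),
    categorical = clamp(round(x), min(prior$values), max(prior$values)),
    norm = if (knob == "sleep_dur_h") clamp(x, 3, 13) else x)
}

#' Calibrate the severity-to-PHQ-8 intercept of a cohort configuration
#'
#' Latent week severity is `intercept + baseline + sum(coef * z_knob) +
#' noise`. The intercept is chosen by seeded Monte Carlo so that the pooled
#' fraction of reporting weeks whose mean PHQ-8 total is >= 10 matches
#' `target_base_rate`. Called automatically by the generators; exposed for
#' inspection.
#'
#' @param config A `cohort_config`.
#' @param n_mc Monte Carlo draws.
#' @return The config with a `$calibration` element (knob moments and
#'   intercept) attached.
#' @export
calibrate_config <- function(config, n_mc = 40000) {
  if (!is.null(config$calibration)) return(config)
  mom <- knob_prior_moments(config$behavior_knob_priors)
  rownames(mom) <- mom$knob
  m <- with_seed(derive_seed(config$seed, "calibrate"), {
    # draw attribute labels, shifted knobs, and noise components
    attrs <- lapply(config$attribute_distributions, function(p)
      sample(names(p), n_mc, replace = TRUE, prob = p))
    lin <- numeric(n_mc)
    kcache <- new.env()
    knob_z <- function(knob) {
      if (!is.null(kcache[[knob]])) return(kcache[[knob]])
      prior <- config$behavior_knob_priors[[knob]]
      x <- draw_knob(prior, n_mc)
      sh <- config$knob_shifts[config$knob_shifts$knob == knob, , drop = FALSE]
      if (nrow(sh)) for (i in seq_len(nrow(sh))) {
        hit <- attrs[[sh$attribute[i]]] == sh$subgroup[i]
        x[hit] <- x[hit] + sh$shift[i] * mom[knob, "sd"]
      }
      x <- knob_support_clamp(knob, x, prior)
      z <- (x - mom[knob, "mean"]) / mom[knob, "sd"]
      kcache[[knob]] <- z
      z
    }
    cc <- config$outcome_coefficients
    if (nrow(cc)) for (i in seq_len(nrow(cc))) {
      hit <- attrs[[cc$attribute[i]]] == cc$subgroup[i]
      lin[hit] <- lin[hit] + cc$coef[i] * knob_z(cc$knob[i])[hit]
    }
    lin + rnorm(n_mc, 0, config$baseline_sd) +
      rnorm(n_mc, 0, config$severity_noise_sd) +
      rnorm(n_mc, 0, config$response_noise_sd /
              sqrt(config$phq8_per_reporting_week))
  })
  intercept <- 10 - unname(quantile(m, 1 - config$target_base_rate))
  if (intercept + 10 < -2 || intercept > 26)
    stop_config("target_base_rate %.3f is not achievable under the configured noise",
                config$target_base_rate)
  config$calibration <- list(knob_moments = mom, intercept = intercept)
  config
}
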