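# Shared fixtures, built once per test run and cached across files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

no_couplings <- function() {
  data.frame(attribute = character(0), subgroup = character(0),
             knob = character(0), coef = numeric(0))
}

no_shifts <- function() {
  data.frame(attribute = character(0), subgroup = character(0),
             knob = character(0), shift = numeric(0))
}

# Two large subgroups with an opposite-signed coupling between morning
# phone use and depression severity: the canonical planted-bias test bed.
# The knob distributions are identical across subgroups, so a
# subgroup-blind model cannot implicitly recover membership from the
# feature value and must learn the majority direction — which misranks
# the minority subgroup.
sex_flip_config <- function(n_participants, seed, ...) {
  cohort_config(
    n_participants = n_participants, seed = seed,
    outcome_coefficients = data.frame(
      attribute = "sex", subgroup = c("Female", "Male"),
      knob = "session_rate_morning", coef = c(-2.5, 2.5)),
    knob_shifts = no_shifts(),
    ...)
}

# Null generator: behaviors and outcomes are uncoupled.
null_config <- function(n_participants, seed, ...) {
  cohort_config(n_participants = n_participants, seed = seed,
                outcome_coefficients = no_couplings(),
                knob_shifts = no_shifts(), ...)
}

# Small full cohort (streams + outcomes + features + labels) reused by
# the harness and pipeline tests.
small_study <- function() {
  fixture("small_study", function() {
    cfg <- cohort_config(n_participants = 24, seed = 42,
                         missingness = list(gps_drop = 0.1,
                                            screen_drop = 0.05,
                                            week_miss = 0))
    cohort <- assemble_cohort(cfg)
    sched <- reporting_weeks(cfg)
    labels <- completeness_filter(build_labels(score_phq8(cohort$phq8),
                                               sched), sched)
    features <- compute_features(cohort)
    list(cfg = cfg, cohort = cohort, schedule = sched, labels = labels,
         features = features)
  })
}

# Independent brute-force pairwise AUC oracle (double loop).
auc_bruteforce <- function(pos, neg) {
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Independent haversine oracle (spherical law of cosines free, explicit
# formula written separately from the package's).
haversine_oracle <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  6371000 * 2 * atan2(sqrt(a), sqrt(1 - a))
}

# Gap-enumeration oracle for nightly sleep (independent reimplementation).
sleep_night_oracle <- function(times, night_start, night_end) {
  x <- sort(times[times >= night_start & times <= night_end])
  if (length(x) < 2) return(NULL)
  best <- NULL
  for (i in seq_len(length(x) - 1)) {
    gap <- x[i + 1] - x[i]
    if (gap >= 3 * 3600 && gap <= 14 * 3600 &&
        (is.null(best) || gap > best$gap)) {
      best <- list(onset = x[i], gap = gap)
    }
  }
  best
}

# The two-subgroup ranking-bias construction: perfect within-subgroup
# separation, every risk in subgroup A above every risk in subgroup B.
fig2_predictions <- function(n_cell = 10) {
  neg_b <- seq(0.00, 0.20, length.out = n_cell)
  pos_b <- seq(0.21, 0.45, length.out = n_cell)
  neg_a <- seq(0.50, 0.70, length.out = n_cell)
  pos_a <- seq(0.71, 0.95, length.out = n_cell)
  preds <- data.table::data.table(
    trial = 1L,
    participant_id = sprintf("P%03d", 1:(4 * n_cell)),
    reporting_week = 1L,
    risk = c(pos_a, neg_a, pos_b, neg_b),
    label = rep(c(TRUE, FALSE, TRUE, FALSE), each = n_cell))
  attrs <- data.frame(
    participant_id = preds$participant_id,
    age_group = rep(c("younger", "older"), each = 2 * n_cell))
  list(preds = preds, attrs = attrs)
}

# Clustered Gaussian risks with a planted subgroup offset.
sim_clustered <- function(n_cl, ni, beta_b = 0.03, icc_sd = 0.05, seed = 1) {
  with_seed(seed, {
    pid <- rep(sprintf("P%04d", seq_len(n_cl)), each = ni)
    g <- rep(sample(c("A", "B"), n_cl, TRUE), each = ni)
    u <- rep(rnorm(n_cl, 0, icc_sd), each = ni)
    y <- 0.3 + beta_b * (g == "B") + u + rnorm(n_cl * ni, 0, 0.03)
    data.frame(risk = y, participant_id = pid, grp = g,
               stringsAsFactors = FALSE)
  })
}

expect_file_exists <- function(path) {
  testthat::expect_true(file.exists(path), label = paste("file", path))
}
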