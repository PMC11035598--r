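test_that("attribute sampling honors marginals and rejects bad ones", {
  cfg <- null_config(40, seed = 1)
  cfg$attribute_distributions <- list(grp = c(A = 1.0))
  prof <- sample_profiles(cfg)
  expect_true(all(prof$grp == "A"))

  bad <- cfg
  bad$attribute_distributions <- list(grp = c(A = 0.6, B = 0.5))
  expect_error(validate_cohort_config(bad), "grp")

  # cohort-scale marginal: observed female fraction within 3 binomial SDs
  big <- fixture("profiles650", function()
    sample_profiles(cohort_config(n_participants = 650, seed = 7)))
  p <- study_attribute_marginals()$sex["Female"]
  expect_lt(abs(mean(big$sex == "Female") - p), 3 * sqrt(p * (1 - p) / 650))
})

test_that("profiles and cohorts are deterministic under a fixed seed", {
  cfg <- cohort_config(n_participants = 10, study_weeks = 4, seed = 5)
  p1 <- sample_profiles(cfg)
  p2 <- sample_profiles(cfg)
  expect_identical(p1, p2)

  d1 <- file.path(tempdir(), "coh-a"); d2 <- file.path(tempdir(), "coh-b")
  assemble_cohort(cfg, dir = d1)
  assemble_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("cohort file", f))
  }
})

test_that("default schedule is reporting weeks 1,4,7,10,13,16", {
  expect_identical(reporting_weeks(cohort_config(n_participants = 1)),
                   c(1L, 4L, 7L, 10L, 13L, 16L))
  expect_identical(
    reporting_weeks(list(reporting_start_week = 2, study_weeks = 9,
                         reporting_interval_weeks = 4)),
    c(2L, 6L))
})

test_that("a fully regular home-bound participant never transits", {
  cfg <- null_config(1, seed = 3, study_weeks = 2,
                     missingness = list(gps_drop = 0, screen_drop = 0,
                                        week_miss = 0))
  cfg$behavior_knob_priors$n_routine_places <-
    list(dist = "categorical", values = 0, probs = 1)
  cfg$behavior_knob_priors$movement_regularity <-
    list(dist = "categorical", values = 1, probs = 1)
  prof <- sample_profiles(cfg)
  st <- generate_streams(prof, cfg)
  d <- haversine_m(st$gps$lat, st$gps$lon, prof$home_lat, prof$home_lon)
  expect_lt(max(d), 100)  # 10 m jitter SD: everything within dwell radius
  cl <- cluster_locations(st$gps)
  expect_identical(cl$n_clusters, 1L)
  expect_equal(mean(cl$transition), 0)
})

test_that("screen events never fall inside the habitual sleep window", {
  cfg <- null_config(1, seed = 11, study_weeks = 2,
                     missingness = list(gps_drop = 0, screen_drop = 0,
                                        week_miss = 0))
  cfg$behavior_knob_priors$sleep_onset_h <-
    list(dist = "categorical", values = 23, probs = 1)
  cfg$behavior_knob_priors$sleep_dur_h <-
    list(dist = "categorical", values = 8.5, probs = 1)
  prof <- sample_profiles(cfg)
  st <- generate_streams(prof, cfg)
  phase <- st$screen$t %% 86400
  inside <- phase > 23 * 3600 | phase < 7.5 * 3600
  expect_equal(sum(inside), 0)
})

test_that("GPS drop probability thins fixes binomially", {
  cfg <- null_config(1, seed = 13, study_weeks = 2,
                     missingness = list(gps_drop = 0.5, screen_drop = 0,
                                        week_miss = 0))
  st <- generate_streams(sample_profiles(cfg), cfg)
  n_slots <- 2 * 7 * 288
  expect_lt(abs(nrow(st$gps) - 0.5 * n_slots),
            3 * sqrt(n_slots * 0.25))
})

test_that("zero couplings calibrate the pooled CSD rate to the target", {
  cfg <- null_config(300, seed = 9,
                     missingness = list(gps_drop = 0, screen_drop = 0,
                                        week_miss = 0))
  lab <- build_labels(generate_outcomes(sample_profiles(cfg), cfg),
                      reporting_weeks(cfg))
  # clustered samples: tolerance at the participant level
  expect_lt(abs(mean(lab$csd) - 0.46), 3 * sqrt(0.46 * 0.54 / 300))
})

test_that("planted coupling signs are recoverable within subgroups", {
  cfg <- sex_flip_config(600, seed = 17,
                         missingness = list(gps_drop = 0, screen_drop = 0,
                                            week_miss = 0))
  prof <- sample_profiles(cfg)
  lab <- build_labels(generate_outcomes(prof, cfg), reporting_weeks(cfg))
  d <- merge(as.data.frame(lab),
             prof[, c("participant_id", "sex", "session_rate_morning")],
             by = "participant_id")
  slope <- function(sub) {
    dd <- d[d$sex == sub, ]
    unname(coef(glm(csd ~ session_rate_morning, binomial(), dd))[2])
  }
  expect_lt(slope("Female"), 0)
  expect_gt(slope("Male"), 0)
})

test_that("PHQ-8 item decomposition respects totals and bounds", {
  for (tot in 0:24) {
    items <- largest_remainder_alloc(tot, rep(1, 8), cap = 3L)
    expect_identical(sum(items), tot)
    expect_true(all(items >= 0 & items <= 3))
  }
  expect_identical(largest_remainder_alloc(0, rep(1, 8)), rep(0L, 8))
  expect_identical(largest_remainder_alloc(24, rep(1, 8)), rep(3L, 8))
  # skewed weights still hit the exact total
  expect_identical(sum(largest_remainder_alloc(13, c(5, 1, 1, 1, 1, 1, 1, 1))),
                   13L)
})

test_that("assembled bundles cover every participant and round-trip", {
  cfg <- cohort_config(n_participants = 5, study_weeks = 4, seed = 23,
                       missingness = list(gps_drop = 0.2, screen_drop = 0.1,
                                          week_miss = 0))
  dir <- file.path(tempdir(), "coh-roundtrip")
  cohort <- assemble_cohort(cfg, dir = dir)
  ids <- cohort$attributes$participant_id
  back <- read_cohort(dir)
  for (tab in list(back$attributes, back$gps, back$screen, back$phq8)) {
    expect_setequal(unique(tab$participant_id), ids)
  }
  expect_equal(back$gps$t, cohort$gps$t)
  expect_equal(back$gps$lat, cohort$gps$lat, tolerance = 1e-6)
  expect_identical(back$manifest$config_hash, cohort$manifest$config_hash)
  expect_identical(back$phq8$total, cohort$phq8$total)
})
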