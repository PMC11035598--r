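day <- 86400

test_that("speeds match an independent haversine oracle", {
  set.seed(4)
  n <- 60
  fx <- data.frame(t = seq(0, by = 300, length.out = n),
                   lat = 40 + cumsum(rnorm(n, 0, 0.001)),
                   lon = -75 + cumsum(rnorm(n, 0, 0.001)))
  cl <- cluster_locations(fx)
  d_or <- mapply(haversine_oracle, fx$lat[-n], fx$lon[-n],
                 fx$lat[-1], fx$lon[-1])
  expect_equal(cl$speed_kmh, c(0, d_or / 300 * 3.6), tolerance = 1e-9)
})

test_that("clustering handles dwell, transit and pure movement", {
  # all fixes at one point
  one <- data.frame(t = seq(0, by = 300, length.out = 50),
                    lat = rep(40, 50), lon = rep(-75, 50))
  cl <- cluster_locations(one)
  expect_identical(cl$n_clusters, 1L)
  expect_equal(mean(cl$transition), 0)

  # two sites 10 km apart with a fast transit between dwell phases
  t1 <- seq(0, by = 300, length.out = 50)
  transit <- seq(50 * 300, by = 300, length.out = 6)
  t2 <- seq(56 * 300, by = 300, length.out = 50)
  lat2 <- 40 + 10 / 111.32
  frac <- seq_along(transit) / length(transit)
  two <- data.frame(
    t = c(t1, transit, t2),
    lat = c(rep(40, 50), 40 + frac * (lat2 - 40), rep(lat2, 50)),
    lon = -75)
  cl2 <- cluster_locations(two)
  expect_identical(cl2$n_clusters, 2L)
  expect_true(all(cl2$transition[51:56]))
  expect_false(any(cl2$transition[c(2:50, 58:106)]))

  # continuous movement at 5 km/h: everything in transition, no clusters
  mv <- data.frame(t = seq(0, by = 300, length.out = 100),
                   lat = 40 + (5 / 111.32 / 12) * (0:99), lon = -75)
  cl3 <- cluster_locations(mv)
  expect_equal(mean(cl3$transition[-1]), 1)
  expect_identical(cl3$n_clusters, 0L)
  expect_equal(compute_location_features(mv, cl3)[["loc_pct_transition"]],
               0.99)  # first fix has no predecessor, counted stationary

  expect_null(cluster_locations(one[1, , drop = FALSE]))
})

test_that("entropy, normalized entropy and home fraction behave", {
  # equal dwell in 4 distant clusters, teleporting with huge time gaps
  mk <- function(lat, t0) data.frame(t = t0 + seq(0, by = 300, length.out = 40),
                                     lat = lat, lon = -75)
  fx <- rbind(mk(40.0, 0), mk(40.1, 10 * day), mk(40.2, 20 * day),
              mk(40.3, 30 * day))
  cl <- cluster_locations(fx)
  f <- compute_location_features(fx, cl)
  expect_identical(cl$n_clusters, 4L)
  expect_equal(f[["loc_entropy"]], log(4), tolerance = 1e-9)
  expect_equal(f[["loc_entropy_norm"]], 1, tolerance = 1e-9)

  # all time at home: entropy 0, home fraction 1
  home <- mk(40, 0)
  fh <- compute_location_features(home, cluster_locations(home))
  expect_equal(fh[["loc_entropy"]], 0)
  expect_equal(fh[["loc_home_frac"]], 1)
  expect_true(is.na(fh[["loc_entropy_norm"]]))  # <2 clusters
})

test_that("circadian movement tracks 24 h periodicity", {
  t <- seq(0, 14 * day - 300, by = 300)
  th <- t / 3600
  sine <- data.frame(t = t, lat = 40 + 0.01 * sin(2 * pi * th / 24),
                     lon = -75)
  set.seed(8)
  noise <- data.frame(t = t, lat = 40 + 0.01 * rnorm(length(t)), lon = -75)
  fr_sine <- ls_band_fraction(th, sine$lat)
  fr_noise <- ls_band_fraction(th, noise$lat)
  # over a 14-day window the 1-hour band is narrower than the spectral
  # resolution (~P^2/T = 1.7 h at 24 h), so leakage caps the fraction
  # well below 1; the sinusoid must still dominate white noise by far
  expect_gt(fr_sine, 0.55)
  # white noise spreads power across the whole 2-26 h grid (band share
  # ~5%, plus sampling noise); the sinusoid concentrates several-fold more
  expect_gt(fr_sine, 5 * fr_noise)
  # spectral oracle on a small input: lm-based explained SS
  tt <- th[1:96]; y <- sine$lat[1:96]
  periods <- seq(2, 26, 0.25)
  oracle <- sapply(periods, function(P) {
    ym <- y - mean(y)
    f <- lm(ym ~ sin(2 * pi * tt / P) + cos(2 * pi * tt / P) - 1)
    sum(fitted(f)^2)
  })
  expect_equal(ls_spectrum(tt, y, periods), oracle, tolerance = 1e-8)
})

test_that("phone features summarize sessions per day and epoch", {
  win <- c(0, 14 * day)
  # one 10-minute session at 09:00 every day
  ev <- do.call(rbind, lapply(0:13, function(d) data.frame(
    t = d * day + c(9 * 3600, 9 * 3600 + 600), event = c("on", "off"))))
  f <- compute_phone_features(ev, win)
  expect_equal(f[["phone_dur_daily_avg"]], 10)
  expect_equal(f[["phone_dur_daily_std"]], 0)
  expect_equal(f[["phone_unlock_daily_avg"]], 1)
  expect_equal(f[["phone_unlock_daily_std"]], 0)
  expect_equal(f[["phone_days_use_morning"]], 14)
  expect_equal(f[["phone_days_use_night"]], 0)
  expect_equal(f[["phone_days_use_total"]], 14)

  # boundary split: 05:50-06:10 contributes 10 min to both epochs
  ev2 <- data.frame(t = c(5 * 3600 + 50 * 60, 6 * 3600 + 10 * 60),
                    event = c("on", "off"))
  f2 <- compute_phone_features(ev2, win)
  expect_equal(f2[["phone_dur_night_avg"]] * 14, 10)
  expect_equal(f2[["phone_dur_morning_avg"]] * 14, 10)
  expect_equal(f2[["phone_unlock_night_avg"]] * 14, 1)  # unlock at start
  expect_equal(f2[["phone_unlock_morning_avg"]], 0)

  # no events: all zeros, never missing
  f0 <- compute_phone_features(NULL, win)
  expect_true(all(f0 == 0))
})

test_that("per-epoch durations sum to the daily duration (conservation)", {
  set.seed(12)
  win <- c(0, 14 * day)
  starts <- sort(runif(60, 0, 14 * day - 4000))
  ends <- starts + runif(60, 60, 3600 * 3)
  ev <- data.frame(t = c(rbind(starts, pmin(ends, c(starts[-1], 14 * day)))),
                   event = rep(c("on", "off"), 60))
  f <- compute_phone_features(ev, win)
  daily <- f[["phone_dur_daily_avg"]]
  by_epoch <- sum(f[paste0("phone_dur_", c("night", "morning", "afternoon",
                                           "evening"), "_avg")])
  expect_equal(by_epoch, daily, tolerance = 1e-9)
})

test_that("sleep inference finds the longest nightly interaction gap", {
  win <- c(0, 14 * day)
  mkev <- function(hours) do.call(rbind, lapply(0:13, function(d)
    data.frame(t = d * day + hours * 3600, event = "on")))
  # quiet 23:00-07:30 -> onset 23:00, duration 8.5 h, SD 0
  ev <- mkev(c(21, 22, 23, 31.5, 33))
  f <- infer_sleep(ev, win)
  expect_equal(f[["sleep_onset_avg"]], 23)
  expect_equal(f[["sleep_duration_avg"]], 8.5)
  expect_equal(f[["sleep_duration_std"]], 0)

  # an extra 03:00 interaction shortens the gap to 03:00-07:30
  f2 <- infer_sleep(mkev(c(21, 22, 23, 27, 31.5, 33)), win)
  expect_equal(f2[["sleep_duration_avg"]], 4.5)
  expect_equal(f2[["sleep_onset_avg"]], 3)

  # circular mean across midnight: alternating 23:30 / 00:30 -> 00:00
  ev3 <- do.call(rbind, lapply(0:13, function(d) {
    onset <- if (d %% 2 == 0) 23.5 else 24.5
    data.frame(t = d * day + c(21, onset, onset + 8) * 3600, event = "on")
  }))
  f3 <- infer_sleep(ev3, win)
  expect_equal(f3[["sleep_onset_avg"]], 0, tolerance = 1e-9)

  # fewer than 7 valid nights: all features missing
  few <- ev[ev$t < 5 * day, , drop = FALSE]
  expect_true(all(is.na(infer_sleep(few, win))))
})

test_that("nightly gaps agree with a brute-force enumeration oracle", {
  set.seed(33)
  win <- c(0, 14 * day)
  ev <- data.frame(t = sort(c(
    runif(250, 0, 14 * day),
    unlist(lapply(0:13, function(d) d * day + c(21.5, 32) * 3600)))),
    event = "on")
  f <- infer_sleep(ev, win, min_nights = 1)
  onsets <- durations <- numeric(0)
  for (d in 0:13) {
    o <- sleep_night_oracle(ev$t, d * day + 20 * 3600, (d + 1) * day + 12 * 3600)
    if (!is.null(o)) {
      onsets <- c(onsets, (o$onset %% day) / 3600)
      durations <- c(durations, o$gap / 3600)
    }
  }
  expect_equal(f[["sleep_duration_avg"]], mean(durations), tolerance = 1e-9)
  ang <- onsets / 24 * 2 * pi
  cm <- (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * 24) %% 24
  expect_equal(f[["sleep_onset_avg"]], cm, tolerance = 1e-9)
})

test_that("windows clip at study start and honor the sufficiency rule", {
  st <- small_study()
  f <- st$features
  expect_identical(nrow(f), 24L * 6L)
  expect_true(all(sensed_feature_names() %in% names(f)))
  # entropy bounds hold wherever defined
  ok <- !is.na(f$loc_entropy)
  expect_true(all(f$loc_entropy[ok] >= 0))
  okn <- !is.na(f$loc_entropy_norm)
  expect_true(all(f$loc_entropy_norm[okn] >= 0 & f$loc_entropy_norm[okn] <= 1))
  expect_true(all(f$loc_pct_transition >= 0 & f$loc_pct_transition <= 1,
                  na.rm = TRUE))
  # a sparse window (99% fixes dropped) voids the location family
  g <- st$cohort$gps[st$cohort$gps$participant_id == "P0001", ]
  keep <- seq(1, nrow(g), by = 100)
  fv <- feature_window(g[keep, ], st$cohort$screen[0, ],
                       c(0, 7 * day * 2))
  expect_true(all(is.na(fv[startsWith(names(fv), "loc_")])))
})
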