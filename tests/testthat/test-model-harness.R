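test_that("subject folds partition participants near-equally", {
  ids <- sprintf("P%03d", 1:650)
  folds <- make_subject_folds(ids, k = 5, seed = 3)
  expect_setequal(names(folds), ids)
  expect_true(all(table(folds) == 130))
  folds2 <- make_subject_folds(sprintf("P%02d", 1:23), k = 5, seed = 3)
  expect_true(max(table(folds2)) - min(table(folds2)) <= 1)
  expect_error(make_subject_folds(c("a", "b"), k = 5), "2 participants")
})

test_that("every sample gets exactly one out-of-fold risk per trial", {
  st <- small_study()
  cv <- fixture("cv_small", function()
    run_cv_trials(small_study()$features, small_study()$labels,
                  n_trials = 2, seed = 7))
  p <- cv$predictions
  expect_identical(nrow(p), 2L * nrow(st$labels))
  keys <- paste(p$trial, p$participant_id, p$reporting_week)
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(p$risk >= 0 & p$risk <= 1))
  # participants stay within one fold per trial
  by_pt <- tapply(p$fold, paste(p$trial, p$participant_id),
                  function(x) length(unique(x)))
  expect_true(all(by_pt == 1))
})

test_that("cross-validation is reproducible under the same seed", {
  st <- small_study()
  cv1 <- fixture("cv_small", function()
    run_cv_trials(small_study()$features, small_study()$labels,
                  n_trials = 2, seed = 7))
  cv2 <- run_cv_trials(st$features, st$labels, n_trials = 2, seed = 7)
  expect_equal(cv1$predictions$risk, cv2$predictions$risk)
  expect_equal(cv1$trial_auc, cv2$trial_auc)
})

test_that("fully separable features reach near-perfect AUC", {
  set.seed(5)
  ids <- sprintf("P%03d", 1:60)
  lab <- data.table::data.table(
    participant_id = rep(ids, each = 2),
    reporting_week = rep(c(1L, 4L), 60),
    mean_total = 0, csd = rep(c(TRUE, FALSE), each = 60))
  feat <- data.table::data.table(
    participant_id = lab$participant_id,
    reporting_week = lab$reporting_week,
    f1 = ifelse(lab$csd, 2, -2) + rnorm(120, 0, 0.05),
    f2 = rnorm(120))
  cv <- run_cv_trials(feat, lab, model_spec("logistic-l2", C = 1),
                      n_trials = 3, seed = 2)
  expect_gt(median(cv$trial_auc), 0.97)
})

test_that("single-class training folds abort the trial with a diagnostic", {
  lab <- data.table::data.table(
    participant_id = rep(sprintf("P%02d", 1:10), each = 2),
    reporting_week = rep(c(1L, 4L), 10),
    mean_total = 20, csd = TRUE)
  feat <- data.table::data.table(
    participant_id = lab$participant_id,
    reporting_week = lab$reporting_week, f1 = rnorm(20))
  expect_error(run_cv_trials(feat, lab, n_trials = 1, seed = 1),
               "single-class")
})

test_that("Platt scaling is rank-preserving and centers symmetric scores", {
  set.seed(6)
  s <- rnorm(2000)
  y <- plogis(2.2 * s) > runif(2000)
  cal <- platt_fit(s, y)
  expect_gt(cal$a, 0)
  expect_lt(abs(cal$b), 0.15)  # balanced symmetric scores: b ~ 0
  r <- platt_apply(cal, s)
  expect_equal(pairwise_auc(r[y], r[!y]), pairwise_auc(s[y], s[!y]),
               tolerance = 1e-12)
  # well-separated scores calibrate to near 0/1
  s2 <- c(rnorm(200, -4, 0.3), rnorm(200, 4, 0.3))
  y2 <- rep(c(FALSE, TRUE), each = 200)
  r2 <- platt_apply(platt_fit(s2, y2), s2)
  expect_lt(max(r2[!y2]), 0.1)
  expect_gt(min(r2[y2]), 0.9)
  expect_warning(platt_fit(rnorm(10), rep(TRUE, 10)), "fallback")
})

test_that("likelihood oracle confirms the Platt intercept on a small grid", {
  set.seed(7)
  s <- rnorm(300)
  y <- plogis(1.5 * s) > runif(300)
  np <- sum(y); nn <- sum(!y)
  tgt <- ifelse(y, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(a, b) {
    p <- plogis(a * s + b)
    -sum(tgt * log(p) + (1 - tgt) * log(1 - p))
  }
  cal <- platt_fit(s, y)
  # fitted point beats every neighbor on a coarse grid around it
  for (da in c(-0.1, 0, 0.1)) for (db in c(-0.1, 0, 0.1)) {
    if (da == 0 && db == 0) next
    expect_gt(nll(cal$a + da, cal$b + db), nll(cal$a, cal$b))
  }
})

test_that("all four model families fit and emit risks in [0, 1]", {
  set.seed(8)
  x <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- plogis(1.5 * x[, 1]) > runif(200)
  specs <- list(model_spec("logistic-l2", C = 0.1),
                model_spec("svm-rbf", C = 1, class_weight = "balanced"),
                model_spec("random-forest", n_estimators = 10, depth = 3),
                model_spec("gbt", n_estimators = 10, depth = 3,
                           learning_rate = 0.1, loss = "deviance"),
                model_spec("gbt", n_estimators = 10, depth = 3,
                           learning_rate = 0.1, loss = "exponential"))
  for (sp in specs) {
    m <- train_risk_model(sp, x, y, seed = 3)
    r <- predict_risk(m, x)
    expect_true(all(r >= 0 & r <= 1), label = sp$family)
    expect_gt(pairwise_auc(r[y], r[!y]), 0.7)
  }
  expect_error(model_spec("gbt", loss = "huber"), "loss")
  expect_error(model_spec("logistic-l2", C = 0.5), "C must")
})

test_that("the naive carry-forward baseline behaves as designed", {
  sched <- c(1L, 4L, 7L)
  # stable participants: later weeks perfectly ranked by week-1 totals
  lab <- data.table::data.table(
    participant_id = rep(sprintf("P%02d", 1:20), each = 3),
    reporting_week = rep(sched, 20),
    mean_total = rep(seq(1, 20), each = 3))
  lab$csd <- lab$mean_total >= 10
  nb <- naive_baseline(lab, sched)
  expect_identical(nrow(nb), 20L * 2L)
  expect_false(any(nb$reporting_week == 1))
  expect_equal(pairwise_auc(nb$risk[nb$label], nb$risk[!nb$label]), 1)
  # all participants share the week-1 value: complete ties, AUC 0.5
  lab2 <- data.table::copy(lab)
  lab2$mean_total[lab2$reporting_week == 1] <- 12
  nb2 <- naive_baseline(lab2, sched)
  expect_equal(pairwise_auc(nb2$risk[nb2$label], nb2$risk[!nb2$label]), 0.5)
})

test_that("with stable symptoms the naive baseline beats a feature-blind null", {
  cfg <- null_config(150, seed = 31,
                     missingness = list(gps_drop = 0, screen_drop = 0,
                                        week_miss = 0))
  sched <- reporting_weeks(cfg)
  lab <- completeness_filter(
    build_labels(generate_outcomes(sample_profiles(cfg), cfg), sched), sched)
  nb <- naive_baseline(lab, sched)
  auc_naive <- pairwise_auc(nb$risk[nb$label], nb$risk[!nb$label])
  null_risk <- with_seed(1, runif(nrow(nb)))
  auc_null <- pairwise_auc(null_risk[nb$label], null_risk[!nb$label])
  expect_gt(auc_naive, 0.75)   # week-to-week stability is high by design
  expect_gt(auc_naive, auc_null + 0.1)
})
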