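linear_model <- function(w) {
  structure(list(w = w), class = "lin_toy")
}
lin_predict <- function(model, x) as.vector(x %*% model$w)

test_that("too few permutations are refused", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(estimate_shapley(linear_model(c(1, 1)), x, n_permutations = 5,
                                predict_fun = lin_predict),
               "minimum of 10")
})

test_that("attributions satisfy efficiency and the dummy axiom", {
  set.seed(14)
  x <- matrix(rnorm(120 * 6), 120, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- plogis(1.5 * x[, 1] - x[, 2]) > runif(120)
  m <- train_risk_model(model_spec("logistic-l2", C = 1), x, y, seed = 1)
  # permutations = background size: the cycled background mean is exact,
  # so the telescoping makes efficiency hold to numerical precision
  sh <- estimate_shapley(m, x[1:30, ], n_permutations = 120, seed = 2,
                         background = x,
                         ids = data.frame(participant_id = sprintf("P%02d", 1:30),
                                          reporting_week = 1L))
  resid <- abs(rowSums(sh$phi) - (sh$prediction - sh$baseline))
  expect_lt(max(resid), 1e-8)
  # features f3..f6 are noise: tiny attributions vs the signal features
  expect_lt(max(sh$ranking$mean_abs_phi[sh$ranking$feature %in%
                                          paste0("f", 3:6)]),
            min(sh$ranking$mean_abs_phi[sh$ranking$feature %in%
                                          c("f1", "f2")]))
  expect_identical(sh$ranking$feature[1], "f1")
  expect_equal(sh$ranking$direction[sh$ranking$feature == "f1"], 1)
  expect_equal(sh$ranking$direction[sh$ranking$feature == "f2"], -1)
  # long-format records align with the matrix
  expect_identical(nrow(sh$records), 30L * 6L)
  expect_equal(sh$records$phi[sh$records$feature == "f1"],
               unname(sh$phi[, "f1"]))
})

test_that("duplicated features share attribution in expectation", {
  set.seed(15)
  x <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(NULL, c("a", "b")))
  x[, 2] <- x[, 1]  # exact duplicate
  m <- linear_model(c(0.5, 0.5))
  means <- sapply(1:8, function(s) {
    sh <- estimate_shapley(m, x, n_permutations = 30, seed = s,
                           predict_fun = lin_predict)
    colMeans(abs(sh$phi))
  })
  expect_equal(mean(means["a", ]), mean(means["b", ]), tolerance = 0.05)
})

test_that("an exactly-ignored feature gets zero attribution", {
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("used", "ignored")))
  sh <- estimate_shapley(linear_model(c(1, 0)), x, n_permutations = 20,
                         seed = 3, predict_fun = lin_predict)
  expect_equal(max(abs(sh$phi[, "ignored"])), 0)
})

test_that("doubling permutations shrinks attribution variance roughly 2x", {
  set.seed(16)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m <- linear_model(c(1, -1, 0.5, 0))
  var_at <- function(P) {
    est <- sapply(1:14, function(s)
      estimate_shapley(m, x[1:5, ], n_permutations = P, seed = 100 + s,
                       background = x, predict_fun = lin_predict)$phi[1, 1])
    var(est)
  }
  ratio <- var_at(16) / var_at(32)
  expect_gt(ratio, 1.1)
  expect_lt(ratio, 4.5)
})

test_that("subgroup slopes recover planted opposite-signed effects", {
  set.seed(17)
  n_pp <- 500
  pid <- sprintf("P%04d", rep(seq_len(n_pp), each = 2))
  grp <- rep(sample(c("A", "B"), n_pp, TRUE), each = 2)
  xv <- rnorm(2 * n_pp)
  eta <- ifelse(grp == "A", -0.8, 0.6) * xv
  y <- plogis(eta) > runif(2 * n_pp)
  x <- cbind(feat = xv, other = rnorm(2 * n_pp))
  attrs <- data.frame(participant_id = sprintf("P%04d", seq_len(n_pp)),
                      grp = grp[seq(1, 2 * n_pp, by = 2)])
  sl <- fit_subgroup_slopes(x, y, pid, attrs, features = "feat")
  a <- sl[sl$subgroup == "A", ]; b <- sl[sl$subgroup == "B", ]
  expect_lt(a$beta, 0); expect_lt(a$ci_high, 0)
  expect_gt(b$beta, 0); expect_gt(b$ci_low, 0)
  expect_lt(abs(a$beta - (-0.8)), 0.25)
  expect_lt(abs(b$beta - 0.6), 0.25)
})

test_that("single-subgroup attributes reduce to the pooled slope", {
  set.seed(18)
  xv <- rnorm(300)
  y <- plogis(0.7 * xv) > runif(300)
  x <- cbind(feat = xv)
  pid <- sprintf("P%03d", 1:300)
  attrs <- data.frame(participant_id = pid, grp = "only")
  sl <- fit_subgroup_slopes(x, y, pid, attrs, features = "feat")
  pooled <- unname(coef(glm(y ~ xv, binomial()))[2])
  expect_equal(sl$beta, pooled, tolerance = 1e-8)
})

test_that("slopes are invariant to affine rescaling of the raw feature", {
  set.seed(19)
  raw <- rnorm(400, 50, 8)
  y <- plogis(0.5 * scale(raw)[, 1]) > runif(400)
  pid <- sprintf("P%03d", 1:400)
  attrs <- data.frame(participant_id = pid,
                      grp = rep(c("A", "B"), 200))
  std <- function(v) (v - mean(v)) / sensebias:::sd_pop(v)
  s1 <- fit_subgroup_slopes(cbind(feat = std(raw)), y, pid, attrs,
                            features = "feat")
  s2 <- fit_subgroup_slopes(cbind(feat = std(7 * raw - 3)), y, pid, attrs,
                            features = "feat")
  expect_equal(s1$beta, s2$beta, tolerance = 1e-9)
})

test_that("consistency flags exactly the opposing significant slopes", {
  ranking <- data.table::data.table(
    feature = c("f1", "f2"), mean_abs_phi = c(0.3, 0.2),
    direction = c(-1, 1))
  slopes <- data.table::data.table(
    attribute = "grp",
    subgroup = c("A", "B", "A", "B"),
    feature = c("f1", "f1", "f2", "f2"),
    beta = c(-0.5, 0.7, 0.4, -0.2),
    se = 0.1,
    ci_low = c(-0.7, 0.5, 0.2, -0.4),
    ci_high = c(-0.3, 0.9, 0.6, 0.0),
    feat_median = 0, feat_q025 = -1, feat_q975 = 1)
  rep <- consistency_report(ranking, slopes)
  # f1 model-negative: B's positive significant slope opposes it
  expect_false(rep$consistent[rep$feature == "f1" & rep$subgroup == "B"])
  expect_true(rep$consistent[rep$feature == "f1" & rep$subgroup == "A"])
  # f2 model-positive: A agrees; B opposes but its CI touches zero
  expect_true(all(rep$consistent[rep$feature == "f2"]))
})
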