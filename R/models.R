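#' Specify a risk-prediction model
#'
#' The model families and hyperparameter grid mirror the common
#' smartphone-sensing depression literature: L2-regularized logistic
#' regression and RBF support vector machines (regularization strength
#' 0.01/0.1/1.0), and tree ensembles — random forest and gradient-boosted
#' trees — with 10 or 100 estimators, depth 3/10/unbounded, optional
#' balanced class weighting (forest/SVM), and GBT learning rates
#' 0.01/0.1/1.0 with deviance or exponential loss. Non-logistic models
#' are calibrated with Platt scaling so the output is a risk in `[0, 1]`.
#'
#' @param family One of `"random-forest"`, `"logistic-l2"`, `"svm-rbf"`,
#'   `"gbt"`.
#' @param C Inverse regularization strength (logistic/SVM).
#' @param class_weight `"unbalanced"` or `"balanced"` (forest/SVM).
#' @param n_estimators Trees in the ensemble (forest/GBT).
#' @param depth Maximum tree depth; `Inf` grows until pure (forest/GBT).
#' @param learning_rate GBT learning rate.
#' @param loss GBT loss: `"deviance"` or `"exponential"`.
#' @param calibrate Fit Platt scaling on an inner split (ignored for
#'   logistic models, which are inherently calibrated).
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("random-forest", "logistic-l2",
                                  "svm-rbf", "gbt"),
                       C = 1.0, class_weight = "unbalanced",
                       n_estimators = 100, depth = Inf,
                       learning_rate = 0.1, loss = "deviance",
                       calibrate = TRUE) {
  family <- match.arg(family)
  if (family %in% c("logistic-l2", "svm-rbf") && !C %in% c(0.01, 0.1, 1.0))
    stop_config("C must be one of 0.01, 0.1, 1.0")
  if (!class_weight %in% c("unbalanced", "balanced"))
    stop_config("class_weight must be 'unbalanced' or 'balanced'")
  if (family %in% c("random-forest", "gbt")) {
    if (!n_estimators %in% c(10, 100))
      stop_config("n_estimators must be 10 or 100")
    if (!(depth %in% c(3, 10) || is.infinite(depth)))
      stop_config("depth must be 3, 10 or Inf (until pure)")
  }
  if (family == "gbt") {
    if (!learning_rate %in% c(0.01, 0.1, 1.0))
      stop_config("learning_rate must be one of 0.01, 0.1, 1.0")
    if (!loss %in% c("deviance", "exponential"))
      stop_config("loss must be 'deviance' or 'exponential'")
  }
  structure(list(family = family, C = C, class_weight = class_weight,
                 n_estimators = n_estimators, depth = depth,
                 learning_rate = learning_rate, loss = loss,
                 calibrate = calibrate),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  extras <- switch(x$family,
    "logistic-l2" = sprintf("C=%g", x$C),
    "svm-rbf" = sprintf("C=%g, %s", x$C, x$class_weight),
    "random-forest" = sprintf("%d trees, depth %s, %s", x$n_estimators,
                              ifelse(is.infinite(x$depth), "unbounded",
                                     x$depth), x$class_weight),
    "gbt" = sprintf("%d trees, depth %s, lr %g, %s loss", x$n_estimators,
                    ifelse(is.infinite(x$depth), "unbounded", x$depth),
                    x$learning_rate, x$loss))
  cat(sprintf("<model_spec> %s (%s)%s\n", x$family, extras,
              if (x$calibrate && x$family != "logistic-l2")
                ", Platt-calibrated" else ""))
  invisible(x)
}

#' Default model: the best-performing configuration
#'
#' Random forest with 100 trees, maximum depth 10 and balanced class
#' weights — the configuration that performed best in the audit this
#' package reproduces.
#'
#' @return A `model_spec`.
#' @export
default_model_spec <- function() {
  model_spec("random-forest", n_estimators = 100, depth = 10,
             class_weight = "balanced")
}

#' The full model grid
#'
#' @return List of `model_spec` objects covering the audited grid.
#' @export
model_grid <- function() {
  grid <- list()
  for (C in c(0.01, 0.1, 1.0)) {
    grid[[length(grid) + 1]] <- model_spec("logistic-l2", C = C)
    for (cw in c("unbalanced", "balanced"))
      grid[[length(grid) + 1]] <- model_spec("svm-rbf", C = C,
                                             class_weight = cw)
  }
  for (ne in c(10, 100)) for (d in c(3, 10, Inf)) {
    for (cw in c("unbalanced", "balanced"))
      grid[[length(grid) + 1]] <- model_spec("random-forest",
                                             n_estimators = ne, depth = d,
                                             class_weight = cw)
    for (lr in c(0.01, 0.1, 1.0)) for (lo in c("deviance", "exponential"))
      grid[[length(grid) + 1]] <- model_spec("gbt", n_estimators = ne,
                                             depth = d, learning_rate = lr,
                                             loss = lo)
  }
  grid
}

# Fit one family on a standardized feature matrix; returns a scoring
# object. Scores are monotone in risk: probabilities for forests and
# logistic, decision values for SVM, margins for GBT.
fit_base_model <- function(spec, x, y, seed) {
  y <- as.logical(y)
  switch(spec$family,
    "logistic-l2" = {
      n <- nrow(x)
      fit <- glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                            family = "binomial", alpha = 0,
                            lambda = 1 / (spec$C * n), standardize = FALSE)
      list(kind = "logistic", fit = fit, score_type = "prob")
    },
    "random-forest" = {
      cw <- if (spec$class_weight == "balanced") {
        tab <- table(factor(y, levels = c(FALSE, TRUE)))
        as.numeric(length(y) / (2 * tab))
      } else c(1, 1)
      fit <- ranger::ranger(
        x = x, y = factor(y, levels = c(FALSE, TRUE)),
        num.trees = spec$n_estimators,
        max.depth = if (is.infinite(spec$depth)) 0 else spec$depth,
        probability = TRUE, class.weights = cw,
        seed = seed, num.threads = 1)
      list(kind = "rf", fit = fit, score_type = "prob")
    },
    "svm-rbf" = {
      yf <- factor(y, levels = c(FALSE, TRUE))
      cw <- if (spec$class_weight == "balanced") {
        tab <- table(yf)
        setNames(as.numeric(length(y) / (2 * tab)), names(tab))
      } else NULL
      fit <- e1071::svm(x = x, y = yf, kernel = "radial", cost = spec$C,
                        class.weights = cw, scale = FALSE)
      # orient decision values so higher means higher risk
      dv <- attr(predict(fit, x[1:min(50, nrow(x)), , drop = FALSE],
                         decision.values = TRUE), "decision.values")[, 1]
      yy <- y[1:min(50, nrow(x))]
      flip <- mean(dv[yy]) < mean(dv[!yy])
      if (is.na(flip)) flip <- FALSE
      list(kind = "svm", fit = fit, flip = flip, score_type = "raw")
    },
    "gbt" = {
      d <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
      params <- list(max_depth = if (is.infinite(spec$depth)) 0 else spec$depth,
                     eta = spec$learning_rate, nthread = 1,
                     tree_method = "hist")
      if (spec$loss == "deviance") {
        params$objective <- "binary:logistic"
        fit <- xgboost::xgb.train(params, d, nrounds = spec$n_estimators,
                                  verbose = 0)
      } else {
        # AdaBoost-style exponential loss via a custom objective
        expobj <- function(preds, dtrain) {
          yy <- 2 * xgboost::getinfo(dtrain, "label") - 1
          e <- exp(-yy * preds)
          list(grad = -yy * e, hess = e)
        }
        fit <- xgboost::xgb.train(c(params, list(base_score = 0.5)), d,
                                  nrounds = spec$n_estimators,
                                  obj = expobj, verbose = 0)
      }
      list(kind = "gbt", loss = spec$loss, fit = fit, score_type = "raw")
    })
}

score_base_model <- function(model, x) {
  switch(model$kind,
    logistic = as.numeric(predict(model$fit, x, type = "response")),
    rf = predict(model$fit, data = x, num.threads = 1)$predictions[, "TRUE"],
    svm = {
      dv <- attr(predict(model$fit, x, decision.values = TRUE),
                 "decision.values")[, 1]
      if (model$flip) -dv else dv
    },
    gbt = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(x),
                   outputmargin = (model$loss == "exponential"))
      as.numeric(p)
    })
}

#' Fit Platt scaling on classifier scores
#'
#' Fits the sigmoid `P(y = 1 | s) = plogis(a s + b)` by maximum likelihood
#' on prior-smoothed targets (Platt's regularization: positives get target
#' `(N+ + 1)/(N+ + 2)`, negatives `1/(N- + 2)`). With a positive fitted
#' slope the map is strictly increasing, so ranking metrics computed from
#' calibrated risks equal those computed from raw scores.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical outcome labels.
#' @return List with slope `a`, intercept `b`, and `fallback` flag (`TRUE`
#'   when the fit degenerated to the identity-like map).
#' @export
platt_fit <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0 || sd(scores) < 1e-12) {
    warning("degenerate calibration fit; using identity-like fallback")
    return(list(a = 1, b = 0, fallback = TRUE))
  }
  tgt <- ifelse(labels, (np + 1) / (np + 2), 1 / (nn + 2))
  fit <- suppressWarnings(glm(tgt ~ scores, family = quasibinomial()))
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  if (!is.finite(a) || !is.finite(b)) {
    warning("Platt fit did not converge; using identity-like fallback")
    return(list(a = 1, b = 0, fallback = TRUE))
  }
  list(a = a, b = b, fallback = FALSE)
}

#' @rdname platt_fit
#' @param calibration A fit from `platt_fit`.
#' @export
platt_apply <- function(calibration, scores) {
  stats::plogis(calibration$a * scores + calibration$b)
}

#' Train a risk model on one training fold
#'
#' Fits the base model and, for non-logistic families with
#' `calibrate = TRUE`, fits Platt scaling on scores cross-fitted over an
#' inner 3-fold split of the training fold (so the calibrator never sees
#' scores the base model produced for its own training rows), then refits
#' the base model on the full fold.
#'
#' @param spec A [model_spec()].
#' @param x Standardized training feature matrix.
#' @param y Logical labels.
#' @param seed Integer seed controlling inner splits and stochastic fits.
#' @return A `risk_model` with `$predict_risk`-compatible contents.
#' @export
train_risk_model <- function(spec, x, y, seed = 1L) {
  y <- as.logical(y)
  if (length(unique(y)) < 2)
    stop_config("single-class training fold: cannot fit a risk model")
  calibrator <- NULL
  if (spec$calibrate && spec$family != "logistic-l2") {
    idx <- with_seed(derive_seed(seed, "inner"), sample.int(length(y)))
    fold <- rep_len(1:3, length(y))[order(idx)]
    sc <- rep(NA_real_, length(y))
    for (f in 1:3) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      m <- fit_base_model(spec, x[tr, , drop = FALSE], y[tr],
                          derive_seed(seed, "inner-fit", f))
      sc[!tr] <- score_base_model(m, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(sc)
    calibrator <- platt_fit(sc[ok], y[ok])
  }
  model <- fit_base_model(spec, x, y, derive_seed(seed, "fit"))
  structure(list(spec = spec, model = model, calibrator = calibrator),
            class = "risk_model")
}

#' Predict calibrated risk in [0, 1]
#'
#' @param object A `risk_model` from [train_risk_model()].
#' @param x Standardized feature matrix.
#' @return Numeric risks in `[0, 1]`.
#' @export
predict_risk <- function(object, x) {
  s <- score_base_model(object$model, x)
  if (!is.null(object$calibrator)) {
    if (object$calibrator$fallback && object$model$score_type == "prob") {
      return(clamp(s, 0, 1))
    }
    return(platt_apply(object$calibrator, s))
  }
  if (object$model$score_type == "prob") return(clamp(s, 0, 1))
  stats::plogis(s)
}
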