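#' Fit the feature preprocessing pipeline on training rows
#'
#' Applies the standard preprocessing used before model fitting:
#' features whose training-set absolute skewness exceeds
#' `skew_threshold` are log-transformed (`log1p` after shifting the
#' training minimum to 0); missing values are filled by iterative
#' chained-equations imputation (per-feature linear models on all other
#' features, mean-initialized, fitted on training rows only); finally
#' every feature is standardized to training mean 0 and SD 1. All
#' statistics and models depend only on the training rows; the returned
#' transform can be re-applied to unseen rows and serialized to JSON.
#'
#' @param features data.frame/data.table with `participant_id`,
#'   `reporting_week` and feature columns.
#' @param train Logical vector (or integer indices) marking training rows.
#' @param skew_threshold Absolute skewness above which a feature is
#'   log-transformed.
#' @param iterations Chained-equation sweeps.
#' @return List with `x` (standardized numeric matrix for all rows, one
#'   column per retained feature) and `transform` (the fitted,
#'   serializable transform).
#' @export
preprocess_features <- function(features, train, skew_threshold = 3,
                                iterations = 8) {
  df <- as.data.frame(features)
  fcols <- setdiff(names(df), c("participant_id", "reporting_week"))
  X <- as.matrix(df[, fcols, drop = FALSE])
  storage.mode(X) <- "double"
  if (is.logical(train)) train <- which(train)
  if (!length(train)) stop_config("training mask is empty")
  all_na <- vapply(fcols, function(j) all(is.na(X[train, j])), logical(1))
  if (any(all_na)) {
    warning(sprintf("dropping all-missing feature(s): %s",
                    paste(fcols[all_na], collapse = ", ")))
    X <- X[, !all_na, drop = FALSE]
    fcols <- fcols[!all_na]
  }
  # log-transform skewed features (statistics from training rows only)
  log_shift <- setNames(rep(NA_real_, length(fcols)), fcols)
  for (j in fcols) {
    xt <- X[train, j]
    xt <- xt[!is.na(xt)]
    if (length(xt) >= 3 && sd(xt) > 1e-12) {
      sk <- e1071::skewness(xt, type = 2)
      if (is.finite(sk) && abs(sk) > skew_threshold) log_shift[j] <- min(xt)
    }
  }
  X <- apply_log(X, log_shift)
  imp <- fit_impute(X, train, iterations)
  Xf <- imp$x
  mu <- colMeans(Xf[train, , drop = FALSE])
  sdv <- apply(Xf[train, , drop = FALSE], 2, sd_pop)
  sdv[sdv < 1e-12] <- 1
  transform <- list(features = fcols, log_shift = as.list(log_shift),
                    impute = imp$models, iterations = iterations,
                    means = as.list(setNames(mu, fcols)),
                    sds = as.list(setNames(sdv, fcols)),
                    train_means = imp$train_means)
  class(transform) <- "feature_transform"
  x <- sweep(sweep(Xf, 2, mu), 2, sdv, "/")
  list(x = x, transform = transform)
}

apply_log <- function(X, log_shift) {
  for (j in names(log_shift)) {
    if (!is.na(log_shift[[j]])) {
      X[, j] <- log1p(pmax(X[, j] - log_shift[[j]], 0))
    }
  }
  X
}

# Iterative chained-equations imputation. Models are fitted on training
# rows with the target observed; stored coefficients from each sweep are
# replayed verbatim when the transform is applied to new data.
fit_impute <- function(X, train, iterations) {
  fcols <- colnames(X)
  train_means <- colMeans(X[train, , drop = FALSE], na.rm = TRUE)
  miss <- is.na(X)
  na_cols <- fcols[colSums(miss) > 0]
  Xf <- X
  for (j in fcols) Xf[miss[, j], j] <- train_means[j]
  models <- list()
  if (length(na_cols) && length(fcols) > 1) {
    for (it in seq_len(iterations)) {
      for (j in na_cols) {
        obs <- intersect(train, which(!miss[, j]))
        others <- setdiff(fcols, j)
        if (length(obs) < length(others) + 2) next
        A <- cbind(1, Xf[obs, others, drop = FALSE])
        fit <- stats::lm.fit(A, Xf[obs, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        models[[length(models) + 1]] <- list(target = j, beta = as.list(beta))
        pred_rows <- which(miss[, j])
        Xf[pred_rows, j] <- cbind(1, Xf[pred_rows, others, drop = FALSE]) %*% beta
      }
    }
  }
  list(x = Xf, models = models,
       train_means = as.list(setNames(train_means, fcols)))
}

#' Apply a fitted feature transform to new rows
#'
#' @param transform A `feature_transform` from [preprocess_features()].
#' @param features New rows in the same layout as the training data.
#' @return Standardized numeric matrix.
#' @export
apply_feature_transform <- function(transform, features) {
  df <- as.data.frame(features)
  X <- as.matrix(df[, transform$features, drop = FALSE])
  storage.mode(X) <- "double"
  X <- apply_log(X, unlist(transform$log_shift)[transform$features])
  miss <- is.na(X)
  tm <- unlist(transform$train_means)
  for (j in colnames(X)) X[miss[, j], j] <- tm[j]
  for (m in transform$impute) {
    j <- m$target
    beta <- unlist(m$beta)
    pred_rows <- which(miss[, j])
    if (length(pred_rows)) {
      others <- setdiff(transform$features, j)
      X[pred_rows, j] <- cbind(1, X[pred_rows, others, drop = FALSE]) %*% beta
    }
  }
  mu <- unlist(transform$means)[colnames(X)]
  sdv <- unlist(transform$sds)[colnames(X)]
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Serialize / deserialize a feature transform
#'
#' @param transform A `feature_transform`.
#' @param path File path for the JSON representation.
#' @return `transform_write` returns `path` invisibly; `transform_read`
#'   returns the `feature_transform`.
#' @export
transform_write <- function(transform, path) {
  writeLines(jsonlite::toJSON(unclass(transform), auto_unbox = TRUE,
                              digits = NA, null = "null", na = "null"),
             path)
  invisible(path)
}

#' @rdname transform_write
#' @export
transform_read <- function(path) {
  tr <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  tr$log_shift <- lapply(tr$log_shift, function(x) if (is.null(x)) NA_real_ else x)
  class(tr) <- "feature_transform"
  tr
}
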