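#' Permutation-sampling Shapley attributions
#'
#' Model-agnostic Shapley value estimation by random feature
#' permutations against an empirical background distribution
#' (interventional semantics). For each permutation a background row is
#' drawn per sample; features are switched from background to actual
#' values in permutation order and the prediction deltas accumulate into
#' the attributions. Within every permutation the deltas telescope to
#' `f(x) - f(z)`, so averaged attributions satisfy the efficiency axiom
#' up to Monte-Carlo error: `sum_j phi_j ~= prediction - baseline`.
#'
#' @param model A `risk_model` (or anything `predict_fun` accepts).
#' @param x Standardized feature matrix to explain.
#' @param n_permutations Number of sampled permutations (>= 10; variance
#'   halves when this doubles).
#' @param seed RNG seed.
#' @param background Background feature matrix (default `x`).
#' @param predict_fun Function `(model, x) -> risk`.
#' @param ids Optional data frame (`participant_id`, `reporting_week`)
#'   aligned with the rows of `x` for the long-format records.
#' @return A `shapley_attribution`: list with `phi` (matrix), `baseline`,
#'   `prediction`, `ranking` (feature, mean_abs_phi, direction — the sign
#'   of the correlation between feature value and attribution), and
#'   `records` (long format).
#' @export
estimate_shapley <- function(model, x, n_permutations = 50, seed = 1L,
                             background = x, predict_fun = predict_risk,
                             ids = NULL) {
  if (n_permutations < 10)
    stop_config("n_permutations = %d is below the minimum of 10", n_permutations)
  m <- ncol(x)
  nr <- nrow(x)
  phi <- matrix(0, nr, m, dimnames = list(NULL, colnames(x)))
  nbg <- nrow(background)
  with_seed(derive_seed(seed, "shapley"), {
    # cycle the background without replacement (reshuffled each epoch) so
    # the sampled background mean tracks the exact baseline closely
    epochs <- ceiling(n_permutations / nbg)
    bg_seq <- unlist(lapply(seq_len(epochs), function(e) sample.int(nbg)))
    for (p in seq_len(n_permutations)) {
      perm <- sample.int(m)
      zrow <- background[bg_seq[p], ]
      cur <- matrix(zrow, nr, m, byrow = TRUE, dimnames = dimnames(x))
      prev <- predict_fun(model, cur)
      for (j in perm) {
        cur[, j] <- x[, j]
        nxt <- predict_fun(model, cur)
        phi[, j] <- phi[, j] + (nxt - prev)
        prev <- nxt
      }
    }
  })
  phi <- phi / n_permutations
  pred <- predict_fun(model, x)
  baseline <- mean(predict_fun(model, background))
  direction <- vapply(seq_len(m), function(j) {
    if (sd(x[, j]) < 1e-12 || sd(phi[, j]) < 1e-12) return(0)
    sign(stats::cor(x[, j], phi[, j]))
  }, numeric(1))
  ranking <- data.table::data.table(
    feature = colnames(x),
    mean_abs_phi = colMeans(abs(phi)),
    direction = direction)
  data.table::setorder(ranking, -mean_abs_phi)
  records <- NULL
  if (!is.null(ids)) {
    records <- data.table::data.table(
      participant_id = rep(ids$participant_id, m),
      reporting_week = rep(ids$reporting_week, m),
      feature = rep(colnames(x), each = nr),
      phi = as.vector(phi),
      feature_value = as.vector(x))
  }
  structure(list(phi = phi, baseline = baseline, prediction = pred,
                 ranking = ranking, records = records,
                 n_permutations = n_permutations),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat(sprintf("<shapley_attribution> %d samples x %d features, %d permutations\n",
              nrow(x$phi), ncol(x$phi), x$n_permutations))
  cat(sprintf("  efficiency residual (mean |sum phi - (pred - baseline)|): %.4g\n",
              mean(abs(rowSums(x$phi) - (x$prediction - x$baseline)))))
  print(head(as.data.frame(x$ranking), 5))
  invisible(x)
}

#' Per-subgroup explanatory logistic slopes
#'
#' For each (attribute, feature) pair fits the explanatory logistic
#' model `CSD ~ feature * subgroup` and reports the marginal slope per
#' subgroup (base slope + interaction; log-odds per standardized unit)
#' with delta-method 95% CIs from a cluster-robust (participant)
#' covariance, together with the subgroup's feature median and 2.5/97.5
#' percentile interval. Quasi-separated fits fall back to a ridge fit for
#' point estimates (CIs unavailable, with a warning).
#'
#' @param x Standardized feature matrix.
#' @param csd Logical outcome per row.
#' @param participant_id Cluster id per row.
#' @param attributes Attribute table.
#' @param features Features to model (default: all columns of `x`).
#' @param attribute_names Attributes to model (default: all).
#' @param adjust Also adjust for the other attributes' main effects.
#' @return data.table of `SubgroupSlope` rows.
#' @export
fit_subgroup_slopes <- function(x, csd, participant_id, attributes,
                                features = colnames(x),
                                attribute_names = NULL, adjust = FALSE) {
  attrs <- as.data.frame(attributes)
  if (is.null(attribute_names))
    attribute_names <- setdiff(names(attrs), "participant_id")
  out <- list()
  for (a in attribute_names) {
    sub_of <- setNames(attrs[[a]], attrs$participant_id)
    g_all <- factor(sub_of[participant_id])
    for (f in features) {
      df <- data.frame(y = as.logical(csd), xv = x[, f], g = g_all,
                       pid = participant_id)
      if (adjust) {
        for (b in setdiff(attribute_names, a)) {
          sub_b <- setNames(attrs[[b]], attrs$participant_id)
          df[[paste0("adj_", b)]] <- factor(sub_b[participant_id])
        }
      }
      adj_terms <- if (adjust)
        paste(c("", grep("^adj_", names(df), value = TRUE)), collapse = " + ")
      else ""
      form <- as.formula(paste("y ~ xv * g", adj_terms))
      single <- nlevels(df$g) < 2
      if (single) form <- as.formula(paste("y ~ xv", adj_terms))
      fit <- suppressWarnings(glm(form, family = binomial(), data = df))
      sep <- !fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
      if (sep) {
        warning(sprintf("quasi-separation for %s x %s; ridge fallback (no CIs)",
                        a, f))
        mm <- model.matrix(form, df)[, -1, drop = FALSE]
        rf <- glmnet::glmnet(mm, df$y, family = "binomial", alpha = 0,
                             lambda = 1e-3)
        cf <- setNames(as.vector(coef(rf))[-1], colnames(mm))
        V <- NULL
      } else {
        cf <- coef(fit)
        V <- sandwich::vcovCL(fit, cluster = df$pid)
      }
      for (g in levels(df$g) %||% "all") {
        if (single && g != levels(df$g)[1] %||% "all") next
        int_term <- paste0("xv:g", g)
        beta <- unname(cf["xv"]) +
          if (!single && int_term %in% names(cf)) unname(cf[int_term]) else 0
        se <- NA_real_
        if (!is.null(V)) {
          if (!single && int_term %in% rownames(V)) {
            se <- sqrt(V["xv", "xv"] + V[int_term, int_term] +
                         2 * V["xv", int_term])
          } else {
            se <- sqrt(V["xv", "xv"])
          }
        }
        xg <- df$xv[as.character(df$g) == g]
        if (single) xg <- df$xv
        out[[length(out) + 1]] <- data.table::data.table(
          attribute = a, subgroup = if (single) levels(df$g)[1] else g,
          feature = f, beta = beta, se = se,
          ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
          feat_median = median(xg),
          feat_q025 = unname(quantile(xg, 0.025)),
          feat_q975 = unname(quantile(xg, 0.975)))
      }
    }
  }
  data.table::rbindlist(out)
}

#' Consistency of model attributions with subgroup associations
#'
#' Joins the model's per-feature attribution direction (from
#' [estimate_shapley()]) with per-subgroup explanatory slopes (from
#' [fit_subgroup_slopes()]) and flags rows where a subgroup's slope whose
#' CI excludes zero *opposes* the model direction — the signature of an
#' unreliable sensed-behavior for that subgroup.
#'
#' @param attribution A `shapley_attribution` (or its `ranking` table).
#' @param slopes Output of [fit_subgroup_slopes()].
#' @return data.table: attribute, subgroup, feature, model_direction,
#'   beta, ci_low, ci_high, significant, consistent (`FALSE` = flagged
#'   INCONSISTENT).
#' @export
consistency_report <- function(attribution, slopes) {
  ranking <- if (inherits(attribution, "shapley_attribution"))
    attribution$ranking else data.table::as.data.table(attribution)
  sl <- data.table::as.data.table(slopes)
  dir_of <- setNames(ranking$direction, ranking$feature)
  sl$model_direction <- dir_of[sl$feature]
  sl$significant <- !is.na(sl$ci_low) & (sl$ci_low > 0 | sl$ci_high < 0)
  sl$consistent <- !(sl$significant & sl$model_direction != 0 &
                       sign(sl$beta) != sl$model_direction)
  cols <- c("attribute", "subgroup", "feature", "model_direction", "beta",
            "ci_low", "ci_high", "significant", "consistent")
  sl[, cols, with = FALSE]
}
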