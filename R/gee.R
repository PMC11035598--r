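#' Choose reference subgroups per attribute and outcome stratum
#'
#' For relatively-healthy (RH) samples the reference is the subgroup with
#' the lowest mean predicted risk across trials; for CSD samples, the
#' highest. An ideal classifier gives RH samples low risk and CSD samples
#' high risk, so coefficients against these references measure excess
#' (RH) or deficit (CSD) risk attributable to subgroup membership. Ties
#' break lexicographically (with a message).
#'
#' @param predictions Prediction records (`participant_id`, `risk`,
#'   `label`).
#' @param attributes Attribute table.
#' @return List with elements `RH` and `CSD`, each a named character
#'   vector attribute -> reference subgroup.
#' @export
select_references <- function(predictions, attributes) {
  preds <- data.table::as.data.table(predictions)
  attrs <- as.data.frame(attributes)
  attr_names <- setdiff(names(attrs), "participant_id")
  pick <- function(stratum_label, take_max) {
    p <- preds[preds$label == stratum_label]
    refs <- setNames(rep(NA_character_, length(attr_names)), attr_names)
    if (nrow(p) == 0) return(refs)
    for (a in attr_names) {
      sub_of <- setNames(attrs[[a]], attrs$participant_id)
      g <- sub_of[p$participant_id]
      m <- tapply(p$risk, g, mean)
      m <- m[sort(names(m))]  # lexicographic tiebreak
      best <- if (take_max) which(m == max(m)) else which(m == min(m))
      if (length(best) > 1)
        message(sprintf("select_references: tie on '%s'; taking '%s'",
                        a, names(m)[best[1]]))
      refs[a] <- names(m)[best[1]]
    }
    refs
  }
  list(RH = pick(FALSE, take_max = FALSE),
       CSD = pick(TRUE, take_max = TRUE))
}

# Gaussian identity-link GEE with exchangeable working correlation and
# cluster-robust (sandwich) covariance. The exchangeable inverse is used
# in closed form, so arbitrarily large clusters cost O(n).
gee_exchangeable <- function(y, X, cluster, max_iter = 25, tol = 1e-10) {
  cluster <- as.character(cluster)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning(sprintf("rank-deficient design; dropping aliased term(s): %s",
                    paste(drop, collapse = ", ")))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  p <- ncol(X)
  n <- length(y)
  beta <- qr.solve(qr(X), y)
  csize <- table(cluster)[unique(cluster)]
  alpha <- 0
  for (it in seq_len(max_iter)) {
    r <- y - as.vector(X %*% beta)
    phi <- sum(r^2) / (n - p)
    s <- rowsum(r, cluster)              # cluster residual sums
    ssq <- rowsum(r^2, cluster)
    ni <- as.vector(rowsum(rep(1, n), cluster))
    npairs <- sum(ni * (ni - 1) / 2)
    alpha <- if (npairs > p) {
      sum((s^2 - ssq) / 2) / ((npairs - p) * phi)
    } else 0
    lo <- -1 / (max(ni) - 1) + 1e-6
    alpha <- clamp(alpha, max(lo, -0.99), 0.99)
    ci <- alpha / (1 + (ni - 1) * alpha)
    SX <- rowsum(X, cluster)
    Sy <- as.vector(rowsum(y, cluster))
    A <- crossprod(X) - crossprod(SX * ci, SX)
    b <- crossprod(X, y) - crossprod(SX * ci, Sy)
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol) break
  }
  # sandwich covariance (scale phi cancels)
  r <- y - as.vector(X %*% beta)
  s <- as.vector(rowsum(r, cluster))
  ni <- as.vector(rowsum(rep(1, n), cluster))
  ci <- alpha / (1 + (ni - 1) * alpha)
  SX <- rowsum(X, cluster)
  Xr <- rowsum(X * r, cluster)
  G <- (Xr - SX * (ci * s)) / (1 - alpha)
  U <- (crossprod(X) - crossprod(SX * ci, SX)) / (1 - alpha)
  Uinv <- solve(U)
  V <- Uinv %*% crossprod(G) %*% Uinv
  list(coefficients = setNames(as.vector(beta), colnames(X)),
       vcov = V, robust_se = setNames(sqrt(pmax(diag(V), 0)), colnames(X)),
       alpha = alpha, phi = phi, n_clusters = length(ni))
}

#' Isolated subgroup effects on predicted risk (GEE)
#'
#' Fits a Gaussian identity-link GEE with exchangeable working
#' correlation, clustered on participant (each participant's repeated
#' samples across reporting weeks and trials share a cluster), regressing
#' predicted risk on dummy-coded subgroup membership across all
#' attributes simultaneously. Coefficients are adjusted mean risk
#' differences versus the attribute's reference subgroup; standard errors
#' are cluster-robust (sandwich); CIs are `coefficient +/- 1.96 se`.
#'
#' @param data Data frame with `risk`, `participant_id` and one column
#'   per attribute.
#' @param references Named character vector attribute -> reference
#'   subgroup.
#' @param attributes_names Attribute columns to include (defaults to the
#'   names of `references`).
#' @return data.table of `GeeResult` rows (term, attribute, subgroup,
#'   coefficient, robust_se, ci_low, ci_high) with working-correlation
#'   `alpha` as an attribute.
#' @export
fit_gee <- function(data, references, attributes_names = names(references)) {
  df <- as.data.frame(data)
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  meta <- data.frame(term = "(Intercept)", attribute = NA_character_,
                     subgroup = NA_character_, stringsAsFactors = FALSE)
  for (a in attributes_names) {
    lev <- sort(unique(df[[a]]))
    ref <- references[[a]]
    if (!ref %in% lev)
      stop_config("reference subgroup '%s' absent from attribute '%s'",
                  ref, a)
    for (g in setdiff(lev, ref)) {
      X <- cbind(X, as.numeric(df[[a]] == g))
      colnames(X)[ncol(X)] <- paste0(a, "=", g)
      meta <- rbind(meta, data.frame(term = paste0(a, "=", g),
                                     attribute = a, subgroup = g,
                                     stringsAsFactors = FALSE))
    }
  }
  if (nrow(df) < ncol(X))
    stop_config("fewer rows (%d) than parameters (%d)", nrow(df), ncol(X))
  fit <- gee_exchangeable(df$risk, X, df$participant_id)
  kept <- names(fit$coefficients)
  meta <- meta[meta$term %in% kept, ]
  res <- data.table::data.table(
    term = kept,
    attribute = meta$attribute[match(kept, meta$term)],
    subgroup = meta$subgroup[match(kept, meta$term)],
    coefficient = unname(fit$coefficients),
    robust_se = unname(fit$robust_se))
  res$ci_low <- res$coefficient - 1.96 * res$robust_se
  res$ci_high <- res$coefficient + 1.96 * res$robust_se
  data.table::setattr(res, "alpha", fit$alpha)
  data.table::setattr(res, "n_clusters", fit$n_clusters)
  res
}

#' Subgroup-isolation analysis over both outcome strata
#'
#' Splits predictions into RH and CSD samples, picks per-stratum
#' reference subgroups ([select_references()]), and fits a separate GEE
#' per stratum so the subgroup base rate cannot drive the estimated
#' effects. By default all trials' out-of-fold risks are stacked (each
#' participant's rows across trials form one cluster); alternatively
#' risks are averaged over trials first.
#'
#' @param predictions Prediction records.
#' @param attributes Attribute table.
#' @param mode `"stacked"` (all trials' rows) or `"trial_mean"` (risks
#'   averaged over trials per sample before the fit).
#' @return List with elements `RH` and `CSD` ([fit_gee()] outputs) plus
#'   `references`.
#' @export
isolate_subgroup_effects <- function(predictions, attributes,
                                     mode = c("stacked", "trial_mean")) {
  mode <- match.arg(mode)
  preds <- data.table::as.data.table(predictions)
  refs <- select_references(preds, attributes)
  if (mode == "trial_mean") {
    risk <- label <- participant_id <- reporting_week <- NULL
    preds <- preds[, list(risk = mean(risk), label = label[1]),
                   by = list(participant_id, reporting_week)]
  }
  attrs <- as.data.frame(attributes)
  dat <- merge(preds, attrs, by = "participant_id")
  out <- list()
  for (stratum in c("RH", "CSD")) {
    d <- as.data.frame(dat[dat$label == (stratum == "CSD")])
    if (nrow(d) == 0 || anyNA(refs[[stratum]])) {
      message(sprintf("isolate_subgroup_effects: no %s samples; stratum skipped",
                      stratum))
      out[stratum] <- list(NULL)
      next
    }
    out[[stratum]] <- fit_gee(d, refs[[stratum]])
  }
  out$references <- refs
  out
}
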