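PIPELINE_STAGES <- c("simulate", "features", "labels", "train", "audit",
                     "isolate", "interpret", "report")

#' Configuration for a full pipeline run
#'
#' @param out_dir Artifact directory (created if needed).
#' @param cohort A [cohort_config()] for synthetic runs, or `NULL` when
#'   the raw-stream artifacts already exist in `out_dir`.
#' @param spec A [model_spec()] for the training stage.
#' @param n_trials Cross-validation trials.
#' @param k Folds per trial.
#' @param min_subgroup Minimum subgroup size for the bias audit.
#' @param shap_permutations Permutations for the attribution stage.
#' @param gee_mode `"stacked"` or `"trial_mean"` (see
#'   [isolate_subgroup_effects()]).
#' @param seed Master seed for all stages.
#' @param stages Stages to run, in order (subset of
#'   simulate/features/labels/train/audit/isolate/interpret/report).
#' @param force Re-run stages whose outputs already exist.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir, cohort = cohort_config(), spec = default_model_spec(),
                       n_trials = 100, k = 5, min_subgroup = 15,
                       shap_permutations = 50, gee_mode = "stacked",
                       seed = 1L, stages = PIPELINE_STAGES, force = FALSE) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop_config("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, cohort = cohort, spec = spec,
                 n_trials = n_trials, k = k, min_subgroup = min_subgroup,
                 shap_permutations = shap_permutations, gee_mode = gee_mode,
                 seed = as.integer(seed),
                 stages = stages[order(match(stages, PIPELINE_STAGES))],
                 force = force),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: `out_dir`, `n_trials`, `k`, `min_subgroup`,
#' `shap_permutations`, `gee_mode`, `seed`, `stages`, `force`, a `cohort`
#' block of [cohort_config()] arguments, and a `model` block of
#' [model_spec()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (is.null(y$cohort)) cohort_config()
            else do.call(cohort_config, y$cohort)
  spec <- if (is.null(y$model)) default_model_spec()
          else do.call(model_spec, y$model)
  run_config(out_dir = y$out_dir %||% ".",
             cohort = cohort, spec = spec,
             n_trials = y$n_trials %||% 100, k = y$k %||% 5,
             min_subgroup = y$min_subgroup %||% 15,
             shap_permutations = y$shap_permutations %||% 50,
             gee_mode = y$gee_mode %||% "stacked",
             seed = y$seed %||% 1L,
             stages = y$stages %||% PIPELINE_STAGES,
             force = isTRUE(y$force))
}

stage_outputs <- function(dir) {
  list(simulate = file.path(dir, c("attributes.csv", "phq8.csv",
                                   "manifest.json")),
       features = file.path(dir, "features.csv"),
       labels = file.path(dir, "labels.csv"),
       train = file.path(dir, c("predictions.csv", "trial_metrics.csv")),
       audit = file.path(dir, c("bias_records.csv", "bias_summary.csv")),
       isolate = file.path(dir, c("gee_RH.csv", "gee_CSD.csv")),
       interpret = file.path(dir, c("attribution_ranking.csv", "slopes.csv",
                                    "consistency.csv")),
       report = file.path(dir, "report.md"))
}

plog <- function(dir, stage, fmt, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(fmt, ...))
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline.log"),
      append = TRUE)
}

#' Run the audit pipeline
#'
#' Executes the configured stages in order — synthesize cohort, extract
#' features, build labels, run cross-validation trials, audit ranking
#' bias, isolate subgroup effects with GEE, interpret with Shapley
#' attributions and per-subgroup slopes, and assemble a markdown report.
#' Every stage writes plain-text artifacts into `config$out_dir` and a
#' line to `pipeline.log`; reruns skip stages whose outputs already exist
#' unless `force` is set, so the pipeline is resumable and stages can be
#' run in isolation on precomputed artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, the artifact directory.
#' @export
run_pipeline <- function(config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  outs <- stage_outputs(dir)
  done <- function(stage) all(file.exists(outs[[stage]]))
  for (stage in config$stages) {
    if (!config$force && done(stage)) {
      plog(dir, stage, "outputs present; skipping")
      next
    }
    switch(stage,
      simulate = {
        if (is.null(config$cohort))
          stop_config("simulate stage requested but no cohort config given")
        cohort <- assemble_cohort(config$cohort, dir = dir)
        plog(dir, stage, "wrote cohort: %d participants, %d GPS, %d screen, %d PHQ-8",
             cohort$manifest$n_participants, cohort$manifest$n_gps,
             cohort$manifest$n_screen, cohort$manifest$n_phq8)
      },
      features = {
        raw <- read_cohort(dir)
        sched <- pipeline_schedule(config, raw)
        feats <- compute_features(list(gps = raw$gps, screen = raw$screen),
                                  schedule = sched)
        write.csv(feats, outs$features, row.names = FALSE)
        plog(dir, stage, "wrote %d feature windows", nrow(feats))
      },
      labels = {
        raw <- read_cohort(dir)
        sched <- pipeline_schedule(config, raw)
        scored <- score_phq8(raw$phq8)
        lab <- completeness_filter(build_labels(scored, sched), sched)
        write.csv(lab, outs$labels, row.names = FALSE)
        plog(dir, stage, "retained %d participants, %d labels",
             length(attr(lab, "retained")), nrow(lab))
      },
      train = {
        feats <- data.table::fread(outs$features)
        lab <- data.table::fread(outs$labels)
        cv <- run_cv_trials(feats, lab, config$spec,
                            n_trials = config$n_trials, k = config$k,
                            seed = derive_seed(config$seed, "train"))
        write.csv(cv$predictions, outs$train[1], row.names = FALSE)
        write.csv(data.frame(trial = seq_along(cv$trial_auc),
                             auc = cv$trial_auc),
                  outs$train[2], row.names = FALSE)
        plog(dir, stage, "median AUC %.3f (%.3f-%.3f) over %d trials",
             cv$summary["median"], cv$summary["ci_low"],
             cv$summary["ci_high"], config$n_trials)
      },
      audit = {
        preds <- data.table::fread(outs$train[1])
        attrs <- read.csv(file.path(dir, "attributes.csv"),
                          check.names = FALSE, colClasses = "character")
        rec <- bias_metrics(preds, attrs,
                            min_participants = config$min_subgroup)
        summ <- summarize_trials(rec, preds, attrs)
        write.csv(rec, outs$audit[1], row.names = FALSE)
        write.csv(summ, outs$audit[2], row.names = FALSE)
        plog(dir, stage, "%d bias records, %d summaries", nrow(rec),
             nrow(summ))
      },
      isolate = {
        preds <- data.table::fread(outs$train[1])
        attrs <- read.csv(file.path(dir, "attributes.csv"),
                          check.names = FALSE, colClasses = "character")
        iso <- isolate_subgroup_effects(preds, attrs, mode = config$gee_mode)
        write.csv(iso$RH, outs$isolate[1], row.names = FALSE)
        write.csv(iso$CSD, outs$isolate[2], row.names = FALSE)
        plog(dir, stage, "GEE terms: RH %d, CSD %d", nrow(iso$RH),
             nrow(iso$CSD))
      },
      interpret = {
        feats <- data.table::fread(outs$features)
        lab <- data.table::fread(outs$labels)
        attrs <- read.csv(file.path(dir, "attributes.csv"),
                          check.names = FALSE, colClasses = "character")
        dat <- merge(feats, lab[, c("participant_id", "reporting_week",
                                    "csd"), with = FALSE],
                     by = c("participant_id", "reporting_week"))
        fcols <- setdiff(names(feats), c("participant_id", "reporting_week"))
        pp <- preprocess_features(dat[, c("participant_id", "reporting_week",
                                          fcols), with = FALSE],
                                  rep(TRUE, nrow(dat)))
        full <- train_risk_model(config$spec, pp$x, dat$csd,
                                 derive_seed(config$seed, "full-model"))
        shap <- estimate_shapley(full, pp$x,
                                 n_permutations = config$shap_permutations,
                                 seed = derive_seed(config$seed, "shap"),
                                 ids = dat[, c("participant_id",
                                               "reporting_week"),
                                           with = FALSE])
        slopes <- fit_subgroup_slopes(pp$x, dat$csd, dat$participant_id,
                                      attrs)
        cons <- consistency_report(shap, slopes)
        write.csv(shap$ranking, outs$interpret[1], row.names = FALSE)
        write.csv(slopes, outs$interpret[2], row.names = FALSE)
        write.csv(cons, outs$interpret[3], row.names = FALSE)
        plog(dir, stage, "%d features ranked, %d slopes, %d inconsistent",
             nrow(shap$ranking), nrow(slopes), sum(!cons$consistent))
      },
      report = {
        write_report(dir)
        plog(dir, stage, "report written")
      })
  }
  invisible(dir)
}

pipeline_schedule <- function(config, raw) {
  if (!is.null(config$cohort)) return(reporting_weeks(config$cohort))
  as.integer(raw$manifest$reporting_weeks)
}

md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  paste(c(paste("|", paste(names(df), collapse = " | "), "|"),
          paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
          apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))),
        collapse = "\n")
}

write_report <- function(dir) {
  outs <- stage_outputs(dir)
  lines <- c("# Ranking-bias audit report", "")
  if (file.exists(outs$train[2])) {
    tm <- read.csv(outs$train[2])
    lines <- c(lines, sprintf(
      "Overall AUC across %d trials: median %.3f (95%% CI %.3f-%.3f).",
      nrow(tm), median(tm$auc), quantile(tm$auc, 0.025),
      quantile(tm$auc, 0.975)), "")
  }
  if (file.exists(outs$audit[2])) {
    lines <- c(lines, "## Ranking-bias metrics by subgroup", "",
               md_table(read.csv(outs$audit[2], check.names = FALSE)), "")
  }
  if (all(file.exists(outs$isolate))) {
    lines <- c(lines, "## Isolated subgroup effects on predicted risk (GEE)",
               "", "### RH samples", "",
               md_table(read.csv(outs$isolate[1], check.names = FALSE)), "",
               "### CSD samples", "",
               md_table(read.csv(outs$isolate[2], check.names = FALSE)), "")
  }
  if (all(file.exists(outs$interpret))) {
    cons <- read.csv(outs$interpret[3], check.names = FALSE)
    lines <- c(lines, "## Attribution vs subgroup associations", "",
               md_table(read.csv(outs$interpret[1], check.names = FALSE)), "",
               "### Flagged inconsistencies", "",
               if (any(!cons$consistent))
                 md_table(cons[!cons$consistent, ]) else "(none)", "")
  }
  writeLines(lines, file.path(dir, "report.md"))
}
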