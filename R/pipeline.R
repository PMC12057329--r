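#' Configuration for the end-to-end PAI pipeline
#'
#' Bundles every stage's settings: input source (a `trial_dataset` or a
#' [sim_config()] to generate one), episode filter, missingness screen,
#' selection hyperparameters for both methods, model-choice policy, PAI
#' variant flags, the RCSI rule and seeds.
#'
#' @param input A `trial_dataset` or a `sim_config` (exactly one source).
#' @param min_sessions Episode criterion (default 2).
#' @param max_missing_fraction Missingness screen threshold (default 0.5).
#' @param boruta List of [boruta_select()] arguments.
#' @param elastic_net List of [elastic_net_select()] arguments.
#' @param loocv_own_arm Use each patient's held-out LOOCV prediction as
#'   their own-arm prediction instead of the full-model fit (default FALSE,
#'   i.e. both counterfactual predictions come from the final full-arm
#'   models).
#' @param rcsi An [rcsi_rule()].
#' @param zero_cell_policy Odds-ratio policy for endpoint tables (pipeline
#'   default `"haldane"` so small subgroups with empty cells still report).
#' @param seed Master seed for imputation, selection and CV folds.
#' @param output_dir Optional directory; when set, [run_pipeline()] writes
#'   the report JSON and per-patient PAI table there.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input, min_sessions = 2,
                            max_missing_fraction = 0.5,
                            boruta = list(), elastic_net = list(),
                            loocv_own_arm = FALSE,
                            rcsi = rcsi_rule(),
                            zero_cell_policy = "haldane",
                            seed = 1L, output_dir = NULL) {
  if (!inherits(input, "trial_dataset") && !inherits(input, "sim_config"))
    stop("input must be a trial_dataset or a sim_config", call. = FALSE)
  structure(list(input = input, min_sessions = min_sessions,
                 max_missing_fraction = max_missing_fraction,
                 boruta = boruta, elastic_net = elastic_net,
                 loocv_own_arm = loocv_own_arm, rcsi = rcsi,
                 zero_cell_policy = zero_cell_policy,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Between-arm sample characteristics table
#'
#' Compares the two arms on each predictor: pooled two-sample t test for
#' continuous covariates, uncorrected 2x2 chi-square for binaries.
#'
#' @param dataset A complete `trial_dataset`.
#' @return Data frame: variable, type, summaries per arm, statistic, p.
#' @export
sample_characteristics <- function(dataset) {
  preds <- predictor_columns(dataset)
  arm <- dataset$arm
  rows <- lapply(preds, function(cn) {
    v <- dataset[[cn]]
    v1 <- v[arm == "CBT"]; v2 <- v[arm == "CAT"]
    u <- unique(v[!is.na(v)])
    if (is.numeric(v) && length(u) > 2) {
      tt <- pooled_two_sample_t(mean(v1, na.rm = TRUE), sd(v1, na.rm = TRUE),
                                sum(!is.na(v1)),
                                mean(v2, na.rm = TRUE), sd(v2, na.rm = TRUE),
                                sum(!is.na(v2)))
      data.frame(variable = cn, type = "continuous",
                 cbt = sprintf("%.2f (%.2f)", mean(v1, na.rm = TRUE),
                               sd(v1, na.rm = TRUE)),
                 cat = sprintf("%.2f (%.2f)", mean(v2, na.rm = TRUE),
                               sd(v2, na.rm = TRUE)),
                 statistic = sprintf("t(%d) = %.2f", tt$df, tt$t),
                 p = tt$p_value)
    } else {
      pos <- if (all(u %in% c(0, 1))) 1 else sort(as.character(u))[length(u)]
      tab <- rbind(c(sum(v1 == pos, na.rm = TRUE),
                     sum(v1 != pos, na.rm = TRUE)),
                   c(sum(v2 == pos, na.rm = TRUE),
                     sum(v2 != pos, na.rm = TRUE)))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        data.frame(variable = cn, type = "binary",
                   cbt = sprintf("%.1f%%", 100 * mean(v1 == pos, na.rm = TRUE)),
                   cat = sprintf("%.1f%%", 100 * mean(v2 == pos, na.rm = TRUE)),
                   statistic = "degenerate", p = NA_real_)
      } else {
        ct <- pearson_chi2_2x2(tab)
        data.frame(variable = cn, type = "binary",
                   cbt = sprintf("%.1f%%", 100 * mean(v1 == pos, na.rm = TRUE)),
                   cat = sprintf("%.1f%%", 100 * mean(v2 == pos, na.rm = TRUE)),
                   statistic = sprintf("X2(1) = %.2f", ct$chi2),
                   p = ct$p_value)
      }
    }
  })
  do.call(rbind, rows)
}

#' Run the full PAI treatment-matching pipeline
#'
#' Executes, in order: episode filter, missingness screen, per-arm
#' random-forest imputation, per-arm encoding, Boruta and elastic-net
#' selection per arm, LOOCV outcome models with evaluation metrics,
#' preferred-method choice (with cross-arm congruence), final per-arm
#' models, counterfactual cross-predictions, PAI computation,
#' optimal/non-optimal classification, the large-benefit subgroup, and the
#' endpoint statistics (RCSI chi-squares and odds ratios at post-treatment
#' and follow-up, full-sample and subgroup mixed ANOVAs, sample
#' characteristics). Fully reproducible from the configuration and seeds.
#'
#' @param config A [pipeline_config()].
#' @return A `pai_report` list: `sample_table`, `selection` (per arm per
#'   method), `metrics` (the LOOCV evaluation table), `preferred`,
#'   `models`, `pai` (per-patient records), `endpoints` (full sample and
#'   subgroup), `log`, `config_echo`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  dataset <- config$input
  if (inherits(dataset, "sim_config")) {
    note("generating synthetic trial (seed %d)", dataset$seed)
    dataset <- generate_trial(dataset)
  }

  n0 <- nrow(dataset)
  dataset <- suppressMessages(
    apply_episode_filter(dataset, config$min_sessions))
  note("episode filter: %d of %d retained", nrow(dataset), n0)

  scr <- suppressMessages(
    screen_missingness(dataset, config$max_missing_fraction))
  dataset <- scr$dataset
  if (length(scr$dropped))
    note("missingness screen dropped: %s", paste(scr$dropped, collapse = ", "))

  arms <- c("CAT", "CBT")
  if (!all(arms %in% dataset$arm))
    stop("empty dataset: need at least one record per arm", call. = FALSE)

  per_arm <- lapply(arms, function(a) {
    sub <- dataset[dataset$arm == a, , drop = FALSE]
    class(sub) <- class(dataset)
    if (anyNA(sub[predictor_columns(sub)])) {
      sub <- impute_rf(sub, seed = child_seed(config$seed, paste0("imp", a)))
      note("imputed missing predictors in arm %s", a)
    }
    sub
  })
  names(per_arm) <- arms
  complete_data <- do.call(rbind, lapply(per_arm, as.data.frame))
  complete_data <- complete_data[order(complete_data$patient_id), ]

  designs <- lapply(per_arm, encode_predictors)

  selection <- list(); metrics <- list()
  for (a in arms) {
    sel_b <- do.call(boruta_select, c(list(design = designs[[a]]),
      config$boruta,
      list(seed = child_seed(config$seed, paste0("bor", a)))))
    sel_e <- do.call(elastic_net_select, c(list(design = designs[[a]]),
      config$elastic_net,
      list(seed = child_seed(config$seed, paste0("enet", a)))))
    selection[[a]] <- list(boruta = sel_b, elastic_net = sel_e)
    metrics[[a]] <- lapply(selection[[a]], function(sel) {
      pred <- loocv_predictions(designs[[a]], sel$selected)
      cv_metrics(pred, designs[[a]]$outcome)
    })
    note("arm %s: boruta selected %d, elastic net selected %d",
         a, length(sel_b$selected), length(sel_e$selected))
  }

  preferred <- select_preferred_method(metrics)
  for (msg in preferred$notes) note("%s", msg)
  note("preferred method: CAT=%s, CBT=%s",
       preferred$choice["CAT"], preferred$choice["CBT"])

  models <- lapply(arms, function(a)
    fit_final_model(designs[[a]], selection[[a]][[preferred$choice[a]]]$selected))
  names(models) <- arms

  # counterfactual predictions for the full sample from both arm models
  yhat_cat <- predict_outcome(models$CAT, complete_data)
  yhat_cbt <- predict_outcome(models$CBT, complete_data)
  if (config$loocv_own_arm) {
    # DeRubeis-style variant: own-arm prediction is the held-out LOOCV one
    for (a in arms) {
      sel <- selection[[a]][[preferred$choice[a]]]$selected
      loo <- loocv_predictions(designs[[a]], sel)
      idx <- match(designs[[a]]$patient_id, complete_data$patient_id)
      if (a == "CAT") yhat_cat[idx] <- loo else yhat_cbt[idx] <- loo
    }
  }

  pai <- compute_pai(yhat_cbt, yhat_cat,
                     patient_id = complete_data$patient_id,
                     received_arm = complete_data$arm)
  pai <- large_benefit_subgroup(pai)
  gc <- attr(pai, "group_counts")
  note("optimal %d / non-optimal %d / no indication %d; |PAI| threshold %.2f",
       gc$counts["optimal"], gc$counts["non_optimal"],
       gc$counts["no_indication"], attr(pai, "subgroup_rule")$threshold)

  endpoints <- compute_endpoints(pai, complete_data, config)

  report <- structure(list(
    sample_table = sample_characteristics(
      structure(complete_data, class = c("trial_dataset", "data.frame"))),
    selection = selection,
    metrics = metrics,
    preferred = preferred,
    models = models,
    pai = pai,
    endpoints = endpoints,
    log = log,
    config_echo = list(seed = config$seed,
                       min_sessions = config$min_sessions,
                       max_missing_fraction = config$max_missing_fraction,
                       loocv_own_arm = config$loocv_own_arm,
                       rcsi = unclass(config$rcsi),
                       zero_cell_policy = config$zero_cell_policy)
  ), class = "pai_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_json(report_summary(report),
                      file.path(config$output_dir, "report.json"))
    write.csv(as.data.frame(pai),
              file.path(config$output_dir, "pai_records.csv"),
              row.names = FALSE)
  }
  report
}

compute_endpoints <- function(pai, complete_data, config) {
  idx <- match(pai$patient_id, complete_data$patient_id)
  baseline <- complete_data$gad7_baseline[idx]
  post <- complete_data$gad7_post[idx]
  followup <- complete_data$gad7_followup[idx]

  rcsi_post <- rcsi_flag(baseline, post, config$rcsi)
  rcsi_follow <- rcsi_flag(baseline, followup, config$rcsi)

  long <- data.frame(
    subject = rep(pai$patient_id, 3),
    group = rep(ifelse(pai$optimal, "optimal", "non_optimal"), 3),
    time = rep(c("baseline", "post", "followup"), each = nrow(pai)),
    score = c(baseline, post, followup))
  long <- long[!is.na(long$group), ]

  full <- list(
    rcsi_post = try_endpoint(pai$optimal, rcsi_post, config),
    rcsi_followup = try_endpoint(pai$optimal, rcsi_follow, config),
    anova = try_silent(suppressMessages(mixed_anova(long))))

  sub <- pai$large_benefit
  subgroup <- if (sum(sub, na.rm = TRUE) >= 4) {
    list(
      n = sum(sub),
      rcsi_post = try_endpoint(pai$optimal[sub], rcsi_post[sub], config),
      rcsi_followup = try_endpoint(pai$optimal[sub], rcsi_follow[sub], config),
      anova = try_silent(suppressMessages(
        mixed_anova(long[long$subject %in% pai$patient_id[sub], ]))))
  } else {
    list(n = sum(sub), note = "subgroup too small for endpoint tests")
  }

  list(full_sample = full, subgroup = subgroup,
       rcsi_rates = c(post = mean(rcsi_post), followup = mean(rcsi_follow)))
}

try_endpoint <- function(optimal, rcsi, config) {
  try_silent(rcsi_endpoint(optimal, rcsi,
                           zero_cell_policy = config$zero_cell_policy))
}

try_silent <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Flatten a pipeline report for JSON serialization
#' @noRd
report_summary <- function(report) {
  list(
    sample_table = report$sample_table,
    metrics = lapply(report$metrics, function(arm)
      lapply(arm, unclass)),
    preferred = unclass(report$preferred),
    selection = lapply(report$selection, function(arm)
      lapply(arm, function(s) list(method = s$method,
                                   selected = s$selected,
                                   decisions = as.list(s$decisions),
                                   weights = as.list(s$weights)))),
    coefficients = lapply(report$models, function(m) as.list(m$coefficients)),
    group_counts = attr(report$pai, "group_counts"),
    subgroup_rule = attr(report$pai, "subgroup_rule"),
    endpoints = rapply(report$endpoints, unclass, how = "replace"),
    log = report$log,
    config = report$config_echo
  )
}

#' @export
print.pai_report <- function(x, ...) {
  cat("PAI treatment-matching pipeline report\n")
  cat("Preferred method:\n"); print(x$preferred)
  cat("LOOCV evaluation metrics:\n")
  for (arm in names(x$metrics)) {
    for (m in names(x$metrics[[arm]])) {
      cat(sprintf("  %-4s %-12s", arm, m))
      print(x$metrics[[arm]][[m]])
    }
  }
  print(x$pai)
  fs <- x$endpoints$full_sample
  if (is.null(fs$rcsi_post$error)) {
    cat(sprintf("RCSI post: optimal %.1f%% vs non-optimal %.1f%% (X2 = %.2f, p = %.3f, OR = %.2f)\n",
                100 * fs$rcsi_post$rates["optimal"],
                100 * fs$rcsi_post$rates["non_optimal"],
                fs$rcsi_post$chi2$chi2, fs$rcsi_post$chi2$p_value,
                fs$rcsi_post$odds_ratio))
  }
  if (is.null(fs$rcsi_followup$error)) {
    cat(sprintf("RCSI follow-up: optimal %.1f%% vs non-optimal %.1f%% (X2 = %.2f, p = %.3f, OR = %.2f)\n",
                100 * fs$rcsi_followup$rates["optimal"],
                100 * fs$rcsi_followup$rates["non_optimal"],
                fs$rcsi_followup$chi2$chi2, fs$rcsi_followup$chi2$p_value,
                fs$rcsi_followup$odds_ratio))
  }
  if (inherits(fs$anova, "mixed_anova_result")) print(fs$anova)
  invisible(x)
}
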