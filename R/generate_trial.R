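#' Generate a synthetic preference trial
#'
#' Draws `n_total` patients: arm by `arm_probability`, allocation route by
#' `randomized_fraction`, covariates from their marginals, attended sessions
#' from a dropout/engager mixture, and outcomes from the linear model
#' described in [sim_config()]. Questionnaire scores are rounded and clipped
#' to their scale ranges. Predictor cells are then masked at `missing_rate`
#' under the configured mechanism (outcomes are never masked).
#'
#' The returned data frame (class `trial_dataset`) carries attributes:
#' `config` (the generating `sim_config`), and `oracle_pai` — each patient's
#' true individual treatment effect (expected post score under CBT minus
#' under CAT, computed before any masking; positive means CAT is truly
#' better), for parameter-recovery studies.
#'
#' @param config A [sim_config()].
#' @return A `trial_dataset` data frame, one row per patient, with columns
#'   `patient_id`, `arm` ("CAT"/"CBT"), `allocation`
#'   ("preference"/"randomized"), `sessions`, one column per covariate, and
#'   `gad7_post`, `gad7_followup`.
#' @examples
#' trial <- generate_trial(sim_config(n_total = 20, seed = 42))
#' table(trial$arm)
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("configuration error: `config` must be a sim_config", call. = FALSE)
  n <- config$n_total
  spec <- config$covariate_spec

  set.seed(child_seed(config$seed, "design"))
  arm <- ifelse(runif(n) < config$arm_probability, "CAT", "CBT")
  allocation <- ifelse(runif(n) < config$randomized_fraction,
                       "randomized", "preference")
  dropout <- runif(n) < config$dropout_rate
  engaged <- pmin(8L, pmax(2L, as.integer(round(
    rnorm(n, config$sessions_mean, config$sessions_sd)))))
  sessions <- ifelse(dropout, sample(0:1, n, replace = TRUE), engaged)

  set.seed(child_seed(config$seed, "covariates"))
  covs <- lapply(spec, function(m) {
    switch(m$type,
      binary = as.integer(runif(n) < m$prevalence),
      continuous = rnorm(n, m$mean, m$sd),
      scale = clip_scale(rnorm(n, m$mean, m$sd), m$range),
      stop("configuration error: unknown covariate type ", m$type,
           call. = FALSE))
  })
  covs <- as.data.frame(covs)

  # Outcome model on the analysis encoding (z by the configured marginals, +/-0.5).
  x <- encode_by_spec(covs, spec)
  lin_prog <- as.vector(x %*% config$beta_prognostic)
  lin_presc <- as.vector(x %*% config$beta_prescriptive)
  intercept <- ifelse(arm == "CAT", config$intercept_cat, config$intercept_cbt)

  set.seed(child_seed(config$seed, "outcome"))
  eta_post <- intercept + lin_prog + ifelse(arm == "CAT", lin_presc, 0)
  gad7_post <- clip_scale(eta_post + rnorm(n, 0, config$noise_sd),
                          .scale_ranges$gad7)
  carry <- config$followup_carry
  gad7_followup <- clip_scale(
    carry * gad7_post + (1 - carry) * covs$gad7_baseline +
      rnorm(n, 0, config$noise_sd),
    .scale_ranges$gad7)

  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    arm = arm, allocation = allocation, sessions = sessions,
    covs,
    gad7_post = gad7_post, gad7_followup = gad7_followup,
    stringsAsFactors = FALSE
  )

  oracle <- oracle_pai_from_encoded(config, x)

  if (config$missing_rate > 0) {
    set.seed(child_seed(config$seed, "missing"))
    pred_cols <- names(spec)
    if (config$missing_mechanism == "MCAR") {
      p_miss <- rep(config$missing_rate, n)
    } else {
      # Severity-dependent nonresponse: logistic in standardized baseline
      # GAD-7; intercept at qlogis(rate) keeps the marginal rate near target.
      z <- x[, "gad7_baseline"]
      p_miss <- plogis(qlogis(config$missing_rate) + z)
    }
    for (cn in pred_cols) {
      mask <- runif(n) < p_miss
      out[[cn]][mask] <- NA
    }
  }

  structure(out,
            class = c("trial_dataset", "data.frame"),
            config = config,
            oracle_pai = oracle,
            provenance = sprintf("synthetic(seed=%d,n=%d)", config$seed, n))
}

#' Encode raw covariates on the generator's analysis scale
#'
#' Continuous/scale covariates standardized by the configured marginal mean/SD;
#' binary flags mapped to -0.5/+0.5.
#' @noRd
encode_by_spec <- function(covs, spec) {
  x <- vapply(names(spec), function(cn) {
    m <- spec[[cn]]
    v <- covs[[cn]]
    if (m$type == "binary") ifelse(v == 1, 0.5, -0.5) else (v - m$mean) / m$sd
  }, numeric(nrow(covs)))
  x <- matrix(x, nrow = nrow(covs),
              dimnames = list(NULL, names(spec)))
  x
}

oracle_pai_from_encoded <- function(config, x) {
  # E[post | CBT] - E[post | CAT]; CAT carries the prescriptive interaction.
  (config$intercept_cbt - config$intercept_cat) -
    as.vector(x %*% config$beta_prescriptive)
}

#' True individual treatment effect for synthetic patients
#'
#' Returns the expected post-treatment GAD-7 score under CBT-GSH minus the
#' expectation under CAT-GSH for each record, from the generating model
#' (ignoring rounding/clipping). Positive values mean CAT-GSH is truly the
#' better arm, matching the PAI sign convention. Records must have complete
#' covariates (use pre-masking values).
#'
#' @param config The generating [sim_config()].
#' @param records A `trial_dataset` (or data frame with the covariate
#'   columns) with no missing covariates.
#' @return Numeric vector of true effects, in GAD-7 points.
#' @export
oracle_true_pai <- function(config, records) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$covariate_spec
  missing_cols <- setdiff(names(spec), names(records))
  if (length(missing_cols))
    stop("records lack covariate columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyNA(records[names(spec)]))
    stop("oracle requires complete covariates (pre-missingness values)",
         call. = FALSE)
  x <- encode_by_spec(records[names(spec)], spec)
  oracle_pai_from_encoded(config, x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Trial dataset: %d patients (%s)\n", nrow(x),
              attr(x, "provenance")))
  tab <- table(factor(x$arm, levels = c("CAT", "CBT")))
  cat(sprintf("  arms: CAT %d / CBT %d; missing predictor cells: %d\n",
              tab["CAT"], tab["CBT"],
              sum(is.na(x[, setdiff(names(x),
                    c("patient_id", "arm", "allocation", "sessions",
                      "gad7_post", "gad7_followup"))]))))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4))
  invisible(x)
}

#' Write a trial dataset to CSV with a JSON configuration sidecar
#'
#' One row per patient, fixed header names (documented in
#' `system.file("extdata", "trial_data_dictionary.csv", package =
#' "paimatch")`). For synthetic datasets the generating configuration and
#' seed are stored alongside in `<path>.json` so the dataset can be
#' regenerated exactly.
#'
#' @param dataset A `trial_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
  cfg <- attr(dataset, "config")
  if (!is.null(cfg)) {
    side <- cfg
    class(side) <- NULL
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trial dataset from CSV
#'
#' @param path CSV written by [write_trial_csv()] or following the same data
#'   dictionary.
#' @return A `trial_dataset` data frame.
#' @export
read_trial_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "arm", "sessions", "gad7_baseline", "gad7_post")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols))
    stop("trial CSV lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(out$patient_id))
    stop("patient_id values must be unique", call. = FALSE)
  structure(out, class = c("trial_dataset", "data.frame"),
            provenance = path)
}
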