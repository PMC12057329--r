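#' Identify candidate predictor columns of a trial dataset
#'
#' Everything except identifiers, arm/allocation, sessions and the outcome
#' scores; baseline GAD-7 is a predictor column but is later held out of the
#' candidate set for forced entry.
#' @noRd
predictor_columns <- function(dataset) {
  setdiff(names(dataset),
          c("patient_id", "arm", "allocation", "sessions",
            "gad7_post", "gad7_followup"))
}

#' Retain patients who met the treatment-episode criterion
#'
#' A treatment episode is defined as attending at least `min_sessions`
#' sessions (NHS Talking Therapies uses 2). Counts retained and excluded are
#' reported via `message()`.
#'
#' @param dataset A `trial_dataset`.
#' @param min_sessions Minimum attended sessions (default 2).
#' @return The filtered `trial_dataset` (attributes preserved; the
#'   `oracle_pai` attribute, if present, is subset accordingly).
#' @export
apply_episode_filter <- function(dataset, min_sessions = 2) {
  if (anyNA(dataset$sessions))
    stop("sessions must be present for all records", call. = FALSE)
  keep <- dataset$sessions >= min_sessions
  message(sprintf("episode filter (>= %d sessions): %d retained, %d excluded",
                  min_sessions, sum(keep), sum(!keep)))
  out <- dataset[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("empty dataset: no patient met the episode criterion", call. = FALSE)
  oracle <- attr(dataset, "oracle_pai")
  if (!is.null(oracle)) attr(out, "oracle_pai") <- oracle[keep]
  attr(out, "config") <- attr(dataset, "config")
  attr(out, "provenance") <- attr(dataset, "provenance")
  class(out) <- class(dataset)
  out
}

#' Drop predictors with too much missing data to impute reliably
#'
#' Predictors whose missing fraction is strictly greater than
#' `max_missing_fraction` are removed from the candidate set (columns
#' dropped). A predictor exactly at the threshold is kept.
#'
#' @param dataset A `trial_dataset`.
#' @param max_missing_fraction Proportion in `[0, 1]` (default 0.5).
#' @return List with `dataset` (columns dropped) and `dropped` (character
#'   vector of removed predictor names).
#' @export
screen_missingness <- function(dataset, max_missing_fraction = 0.5) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  preds <- predictor_columns(dataset)
  frac <- vapply(dataset[preds], function(v) mean(is.na(v)), numeric(1))
  dropped <- preds[frac > max_missing_fraction]
  if (length(dropped)) {
    message("dropping predictors with > ",
            round(100 * max_missing_fraction), "% missing: ",
            paste(sprintf("%s (%.0f%%)", dropped, 100 * frac[dropped]),
                  collapse = ", "))
    keep_attrs <- attributes(dataset)[c("config", "oracle_pai", "provenance")]
    dataset <- dataset[, setdiff(names(dataset), dropped), drop = FALSE]
    for (a in names(keep_attrs))
      if (!is.null(keep_attrs[[a]])) attr(dataset, a) <- keep_attrs[[a]]
  }
  list(dataset = dataset, dropped = dropped)
}

#' Iterative random-forest imputation of missing predictor values
#'
#' missForest-style chained imputation: missing cells are initialized with
#' the column mean (continuous) or mode (binary/categorical), then each
#' incomplete variable is regressed on all other predictors with a random
#' forest and its missing cells refreshed, cycling in order of increasing
#' missingness. Iteration stops when the change between successive
#' imputations (sum of squared differences for continuous variables,
#' disagreement count for categorical) increases, or after `max_iter`
#' sweeps; the previous sweep's values are returned when the criterion
#' rises. Observed cells are never altered. Intended to be called once per
#' treatment arm so that no information crosses arms.
#'
#' @param dataset A `trial_dataset` (typically one arm's subset).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param max_iter Maximum sweeps (default 10).
#' @param num_trees Trees per forest (default 100).
#' @return The completed `trial_dataset`.
#' @export
impute_rf <- function(dataset, seed = 1L, max_iter = 10, num_trees = 100) {
  preds <- predictor_columns(dataset)
  n_miss <- vapply(dataset[preds], function(v) sum(is.na(v)), integer(1))
  if (!any(n_miss > 0)) return(dataset)
  all_missing <- preds[n_miss == nrow(dataset)]
  if (length(all_missing))
    stop("unimputable variable (entirely missing): ",
         paste(all_missing, collapse = ", "), call. = FALSE)

  work <- as.data.frame(dataset[preds])
  is_cat <- vapply(work, function(v) {
    u <- unique(v[!is.na(v)])
    is.character(v) || is.factor(v) || all(u %in% c(0, 1))
  }, logical(1))
  miss_idx <- lapply(work, function(v) which(is.na(v)))

  # mean/mode initialization
  for (cn in preds[n_miss > 0]) {
    v <- work[[cn]]
    fill <- if (is_cat[[cn]]) {
      tab <- table(v[!is.na(v)])
      mode_lv <- names(tab)[which.max(tab)]
      if (is.numeric(v)) as.numeric(mode_lv) else mode_lv
    } else mean(v, na.rm = TRUE)
    v[is.na(v)] <- fill
    work[[cn]] <- v
  }

  order_cols <- preds[n_miss > 0][order(n_miss[n_miss > 0])]
  prev <- work
  prev_crit <- c(cont = Inf, cat = Inf)
  set.seed(child_seed(seed, "impute"))
  for (iter in seq_len(max_iter)) {
    for (cn in order_cols) {
      idx <- miss_idx[[cn]]
      ytrain <- work[[cn]][-idx]
      train <- work[-idx, setdiff(preds, cn), drop = FALSE]
      test <- work[idx, setdiff(preds, cn), drop = FALSE]
      if (is_cat[[cn]]) {
        fit <- ranger::ranger(x = train, y = factor(ytrain),
                              num.trees = num_trees,
                              seed = child_seed(seed, paste0(cn, iter)),
                              num.threads = 1)
        pred <- as.character(predict(fit, data = test,
                                     num.threads = 1)$predictions)
        if (is.numeric(work[[cn]])) pred <- as.numeric(pred)
        work[[cn]][idx] <- pred
      } else {
        fit <- ranger::ranger(x = train, y = ytrain, num.trees = num_trees,
                              seed = child_seed(seed, paste0(cn, iter)),
                              num.threads = 1)
        work[[cn]][idx] <- predict(fit, data = test,
                                   num.threads = 1)$predictions
      }
    }
    # missForest stopping criterion on successive imputations
    cont_cols <- order_cols[!is_cat[order_cols]]
    cat_cols <- order_cols[is_cat[order_cols]]
    crit <- c(
      cont = if (length(cont_cols)) {
        num <- sum(vapply(cont_cols, function(cn)
          sum((work[[cn]] - prev[[cn]])^2), numeric(1)))
        den <- sum(vapply(cont_cols, function(cn)
          sum(work[[cn]]^2), numeric(1)))
        num / den
      } else 0,
      cat = if (length(cat_cols)) {
        sum(vapply(cat_cols, function(cn)
          sum(work[[cn]] != prev[[cn]]), numeric(1)))
      } else 0
    )
    if (iter > 1 && all(crit >= prev_crit)) {
      work <- prev
      break
    }
    prev_crit <- crit
    prev <- work
  }

  out <- dataset
  for (cn in order_cols) out[[cn]] <- work[[cn]]
  out
}

#' Encode predictors into an analysis design matrix
#'
#' Continuous predictors are standardized into z-scores using this dataset's
#' mean and SD; binary predictors are dummy coded -0.5/+0.5 with the +0.5
#' level fixed alphabetically (the later level name gets +0.5) and the
#' mapping recorded; multi-level categoricals are first collapsed to binary
#' via `collapse` (named list: name of the positive level set per
#' predictor). Baseline GAD-7 is encoded like any continuous predictor but
#' held outside the candidate set as the forced covariate. Zero-variance
#' predictors are dropped with a warning. When the dataset has an
#' `allocation` column, the allocation route joins the candidate set as a
#' derived binary `preference` flag.
#'
#' Encoding statistics are computed on the dataset given (call per arm to
#' keep arms independent); [apply_encoding()] re-applies a stored encoding to
#' new raw data, as needed for cross-arm counterfactual scoring.
#'
#' @param dataset A complete (post-imputation) `trial_dataset`.
#' @param outcome Outcome column (default `"gad7_post"`).
#' @param forced Forced-entry covariate column (default `"gad7_baseline"`).
#' @param collapse Optional named list mapping a predictor name to the
#'   character vector of raw levels that should code +0.5 after collapsing.
#' @return A `design_matrix` object: list with `values` (n x p numeric
#'   matrix), `predictor_names`, `encoding_meta` (data frame: name, type,
#'   center, scale, positive_level), `outcome`, `forced_covariate`,
#'   `forced_meta`, `arm`, `patient_id`.
#' @export
encode_predictors <- function(dataset, outcome = "gad7_post",
                              forced = "gad7_baseline", collapse = list()) {
  preds <- predictor_columns(dataset)
  if (anyNA(dataset[preds]))
    stop("dataset must be complete before encoding (impute first)",
         call. = FALSE)
  raw <- as.data.frame(dataset[preds])

  for (cn in names(collapse)) {
    if (cn %in% names(raw))
      raw[[cn]] <- ifelse(raw[[cn]] %in% collapse[[cn]], "yes", "no")
  }

  # allocation route enters the candidate set as a derived preference flag
  if ("allocation" %in% names(dataset) && !"preference" %in% preds) {
    raw$preference <- ifelse(dataset$allocation == "preference", "yes", "no")
    preds <- c(preds, "preference")
  }

  meta <- list()
  cols <- list()
  for (cn in preds) {
    v <- raw[[cn]]
    u <- sort(unique(v))
    is_binaryish <- is.character(v) || is.factor(v) || is.logical(v) ||
      all(u %in% c(0, 1))
    if (length(u) < 2) {
      warning("zero-variance predictor dropped: ", cn, call. = FALSE)
      meta[[cn]] <- data.frame(name = cn, type = "dropped",
                               center = NA_real_, scale = NA_real_,
                               positive_level = NA_character_)
      next
    }
    if (is_binaryish && length(u) == 2) {
      lv <- sort(as.character(u))          # alphabetical: later level -> +0.5
      pos <- lv[2]
      cols[[cn]] <- ifelse(as.character(v) == pos, 0.5, -0.5)
      meta[[cn]] <- data.frame(name = cn, type = "binary",
                               center = NA_real_, scale = NA_real_,
                               positive_level = pos)
    } else {
      m <- mean(v); s <- sd(v)
      if (s == 0) {                        # constant after numeric check
        warning("zero-variance predictor dropped: ", cn, call. = FALSE)
        meta[[cn]] <- data.frame(name = cn, type = "dropped",
                                 center = NA_real_, scale = NA_real_,
                                 positive_level = NA_character_)
        next
      }
      cols[[cn]] <- (v - m) / s
      meta[[cn]] <- data.frame(name = cn, type = "continuous",
                               center = m, scale = s,
                               positive_level = NA_character_)
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL

  kept <- names(cols)
  if (!forced %in% kept)
    stop("forced covariate ", forced, " absent or degenerate", call. = FALSE)
  candidate <- setdiff(kept, forced)
  values <- do.call(cbind, cols[candidate])
  colnames(values) <- candidate

  structure(list(
    values = values,
    predictor_names = candidate,
    encoding_meta = meta,
    outcome = dataset[[outcome]],
    outcome_name = outcome,
    forced_covariate = cols[[forced]],
    forced_name = forced,
    arm = dataset$arm,
    patient_id = dataset$patient_id
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d patients x %d candidate predictors\n",
              nrow(x$values), length(x$predictor_names)))
  cat(sprintf("  outcome: %s; forced covariate: %s\n",
              x$outcome_name, x$forced_name))
  n_bin <- sum(x$encoding_meta$type == "binary")
  n_cont <- sum(x$encoding_meta$type == "continuous")
  cat(sprintf("  encoding: %d binary (+/-0.5), %d continuous (z)\n",
              n_bin, n_cont))
  invisible(x)
}

#' Re-apply a stored encoding to new raw data
#'
#' Encodes raw predictor columns with a previously computed
#' `encoding_meta` — the means/SDs and level mappings from the fitting
#' arm — so that a model can score patients from the other arm on the scale
#' it was trained on.
#'
#' @param dataset Raw (complete) `trial_dataset` rows.
#' @param encoding_meta The `encoding_meta` data frame of a `design_matrix`
#'   or the snapshot stored in an `arm_model`.
#' @param collapse As in [encode_predictors()].
#' @return Numeric matrix with one column per non-dropped predictor in
#'   `encoding_meta` (forced covariate included under its own name).
#' @export
apply_encoding <- function(dataset, encoding_meta, collapse = list()) {
  raw <- as.data.frame(dataset)
  for (cn in names(collapse)) {
    if (cn %in% names(raw))
      raw[[cn]] <- ifelse(raw[[cn]] %in% collapse[[cn]], "yes", "no")
  }
  if (!"preference" %in% names(raw) && "allocation" %in% names(raw))
    raw$preference <- ifelse(raw$allocation == "preference", "yes", "no")
  keep <- encoding_meta[encoding_meta$type != "dropped", , drop = FALSE]
  missing_cols <- setdiff(keep$name, names(raw))
  if (length(missing_cols))
    stop("schema error: missing predictor columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- vapply(seq_len(nrow(keep)), function(i) {
    m <- keep[i, ]
    v <- raw[[m$name]]
    if (anyNA(v))
      stop("schema error: missing values in ", m$name, call. = FALSE)
    if (m$type == "binary") {
      ifelse(as.character(v) == m$positive_level, 0.5, -0.5)
    } else {
      (v - m$center) / m$scale
    }
  }, numeric(nrow(raw)))
  out <- matrix(out, nrow = nrow(raw), dimnames = list(NULL, keep$name))
  out
}
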