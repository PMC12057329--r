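#' Assemble the regression model matrix: intercept + selected + forced
#' @noRd
model_matrix_for <- function(design, selected) {
  bad <- setdiff(selected, design$predictor_names)
  if (length(bad))
    stop("unknown predictors: ", paste(bad, collapse = ", "), call. = FALSE)
  sel_part <- if (length(selected))
    design$values[, selected, drop = FALSE] else NULL
  mm <- cbind(rep(1, length(design$outcome)), sel_part,
              design$forced_covariate)
  colnames(mm) <- c("(Intercept)", selected,
                    if (!is.null(design$forced_covariate)) design$forced_name)
  mm
}

#' Leave-one-out cross-validated predictions
#'
#' For each patient, an ordinary least squares model (selected predictors +
#' forced baseline covariate + intercept) is fit on the other n-1 patients
#' and the held-out patient's outcome predicted from that fit. Computed via
#' the exact leave-one-out identity for linear smoothers,
#' `yhat(-i) = y_i - e_i / (1 - h_ii)`, which reproduces the n refits to
#' machine precision.
#'
#' @param design A `design_matrix`.
#' @param selected Character vector of selected candidate predictor names.
#' @return Numeric vector of held-out predictions, length n.
#' @export
loocv_predictions <- function(design, selected) {
  mm <- model_matrix_for(design, selected)
  y <- design$outcome
  n <- nrow(mm)
  if (n < ncol(mm) + 2)
    stop("need n >= number of coefficients + 2", call. = FALSE)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm))
    stop("singular fit: design is rank deficient", call. = FALSE)
  fit <- lm.fit(mm, y)
  h <- rowSums(qr.Q(qr_mm)[, seq_len(qr_mm$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-10)) {
    folds <- which(h > 1 - 1e-10)
    stop("singular fit in fold(s) ", paste(folds, collapse = ", "),
         ": observation determines its own prediction", call. = FALSE)
  }
  y - fit$residuals / (1 - h)
}

#' Held-out prediction accuracy metrics
#'
#' RMSE and MAE in outcome units (GAD-7 points), Pearson r between predicted
#' and observed, and two R-squared variants: `r2`, the variance-explained
#' form 1 - SSE/SST on held-out predictions (can be negative), and
#' `r2_pearson = r^2`. The two differ for cross-validated predictions, so
#' both are reported.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 3).
#' @return A `cv_metrics` object (list: rmse, mae, r, r2, r2_pearson, n).
#' @export
cv_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 3)
  if (sd(observed) == 0)
    stop("constant observed outcome: correlation undefined", call. = FALSE)
  err <- observed - predicted
  r <- cor(predicted, observed)
  structure(list(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    r = r,
    r2 = 1 - sum(err^2) / sum((observed - mean(observed))^2),
    r2_pearson = r^2,
    n = length(observed)
  ), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.3f  MAE %.3f  r %.3f  R2 %.3f (r^2 %.3f)  n=%d\n",
              x$rmse, x$mae, x$r, x$r2, x$r2_pearson, x$n))
  invisible(x)
}

#' Choose the preferred selection method per arm
#'
#' Applies the "lowest error and highest correlation" rule per arm: a method
#' that is at least as good on RMSE, MAE and r (and strictly better on at
#' least one) wins. When the two methods tie exactly on every metric (as
#' happens when both select the same variables), the arm defers to the other
#' arm's winner so both arms use the same method (congruence). If neither
#' method dominates, lower RMSE decides and the conflict is noted. If
#' everything ties everywhere, the default is elastic net.
#'
#' @param metrics Nested list: `metrics[[arm]][[method]]` is a
#'   [cv_metrics()] object; two methods per arm.
#' @return A `method_choice` object: list with `choice` (named character,
#'   per arm), `notes` (character vector of logged decisions).
#' @export
select_preferred_method <- function(metrics) {
  arms <- names(metrics)
  stopifnot(length(arms) == 2)
  notes <- character(0)

  score <- function(m) c(rmse = m$rmse, mae = m$mae, r = m$r)
  per_arm <- lapply(arms, function(arm) {
    ms <- metrics[[arm]]
    methods <- names(ms)
    stopifnot(length(methods) == 2)
    a <- score(ms[[1]]); b <- score(ms[[2]])
    if (isTRUE(all.equal(a, b, tolerance = 1e-12))) {
      list(winner = NA_character_, tie = TRUE, methods = methods)
    } else {
      a_dom <- a["rmse"] <= b["rmse"] && a["mae"] <= b["mae"] &&
        a["r"] >= b["r"]
      b_dom <- b["rmse"] <= a["rmse"] && b["mae"] <= a["mae"] &&
        b["r"] >= a["r"]
      if (a_dom && !b_dom) list(winner = methods[1], tie = FALSE)
      else if (b_dom && !a_dom) list(winner = methods[2], tie = FALSE)
      else {
        w <- methods[which.min(c(a["rmse"], b["rmse"]))]
        list(winner = w, tie = FALSE,
             conflict = "metrics disagree; resolved by lower RMSE")
      }
    }
  })
  names(per_arm) <- arms

  choice <- setNames(rep(NA_character_, 2), arms)
  for (arm in arms) {
    pa <- per_arm[[arm]]
    if (!pa$tie) {
      choice[arm] <- pa$winner
      if (!is.null(pa$conflict))
        notes <- c(notes, sprintf("%s: %s", arm, pa$conflict))
    }
  }
  for (arm in arms) {
    if (is.na(choice[arm])) {
      other <- setdiff(arms, arm)
      if (!is.na(choice[other])) {
        choice[arm] <- choice[other]
        notes <- c(notes, sprintf(
          "%s: methods tied on all metrics; deferring to %s's winner (%s)",
          arm, other, choice[other]))
      } else {
        choice[arm] <- "elastic_net"
        notes <- c(notes,
                   sprintf("%s: all methods tied everywhere; defaulting to elastic_net", arm))
      }
    }
  }
  structure(list(choice = choice, notes = notes), class = "method_choice")
}

#' @export
print.method_choice <- function(x, ...) {
  for (arm in names(x$choice))
    cat(sprintf("  %s: %s\n", arm, x$choice[arm]))
  if (length(x$notes)) cat(paste0("  note: ", x$notes, "\n"), sep = "")
  invisible(x)
}

#' Fit the final per-arm outcome model
#'
#' Single OLS fit on the arm's full analysis sample: selected predictors +
#' forced baseline covariate + intercept. The encoding snapshot travels with
#' the model so patients from the other arm can be scored on the same scale.
#'
#' @param design The arm's `design_matrix`.
#' @param selected Selected candidate predictor names.
#' @return An `arm_model`: list with `arm`, `predictor_names`,
#'   `coefficients` (intercept, selected, forced), `encoding_meta`,
#'   `forced_name`, `outcome_name`, `fitted`, `sigma`.
#' @export
fit_final_model <- function(design, selected) {
  mm <- model_matrix_for(design, selected)
  y <- design$outcome
  if (qr(mm)$rank < ncol(mm))
    stop("singular fit: design is rank deficient", call. = FALSE)
  fit <- lm.fit(mm, y)
  structure(list(
    arm = unique(design$arm),
    predictor_names = selected,
    coefficients = setNames(fit$coefficients, colnames(mm)),
    encoding_meta = design$encoding_meta,
    forced_name = design$forced_name,
    outcome_name = design$outcome_name,
    fitted = as.vector(mm %*% fit$coefficients),
    sigma = sqrt(sum(fit$residuals^2) /
                   max(1, length(y) - ncol(mm)))
  ), class = "arm_model")
}

#' @export
print.arm_model <- function(x, ...) {
  cat(sprintf("Outcome model for arm %s (%s ~ %d predictors + %s)\n",
              paste(x$arm, collapse = "/"), x$outcome_name,
              length(x$predictor_names), x$forced_name))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict post-treatment outcome for (possibly cross-arm) patients
#'
#' Re-encodes the raw patient rows with the model's stored encoding snapshot
#' and evaluates the linear predictor. Predictions are returned as-is (not
#' clipped to the questionnaire scale).
#'
#' @param model An `arm_model`.
#' @param dataset Raw (complete) `trial_dataset` rows to score.
#' @param collapse As in [encode_predictors()].
#' @return Numeric vector of predicted post GAD-7 scores.
#' @export
predict_outcome <- function(model, dataset, collapse = list()) {
  enc <- apply_encoding(dataset, model$encoding_meta, collapse = collapse)
  need <- c(model$predictor_names, model$forced_name)
  missing_cols <- setdiff(need, colnames(enc))
  if (length(missing_cols))
    stop("schema error: encoded data lacks ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  mm <- cbind(1, enc[, need, drop = FALSE])
  as.vector(mm %*% model$coefficients)
}
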