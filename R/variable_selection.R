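#' Build the shadow-augmented predictor matrix for one Boruta iteration
#'
#' Standard variant: every candidate gets a row-permuted shadow copy, so the
#' augmented matrix is exactly twice as wide. The `two_shadow` variant adds
#' only two shadows (one permuted continuous column, one permuted binary
#' column, falling back to any column when a kind is absent).
#' @noRd
boruta_augment <- function(x, two_shadow = FALSE) {
  n <- nrow(x)
  if (!two_shadow) {
    shadows <- apply(x, 2, function(col) col[sample.int(n)])
    colnames(shadows) <- paste0("shadow_", colnames(x))
  } else {
    is_bin <- apply(x, 2, function(col) all(col %in% c(-0.5, 0.5)))
    pick <- c(
      if (any(!is_bin)) sample(which(!is_bin), 1) else sample(ncol(x), 1),
      if (any(is_bin)) sample(which(is_bin), 1) else sample(ncol(x), 1)
    )
    shadows <- x[, pick, drop = FALSE]
    shadows <- apply(shadows, 2, function(col) col[sample.int(n)])
    colnames(shadows) <- c("shadow_cont", "shadow_bin")
  }
  cbind(x, shadows)
}

#' Boruta all-relevant variable selection
#'
#' Implements the shadow-feature random-forest selection loop: at each
#' iteration the candidate matrix is augmented with row-permuted shadow
#' copies of every candidate, a random forest is fit with permutation
#' importance, and each still-undecided candidate scores a "hit" when its
#' importance exceeds the best shadow importance. After each iteration a
#' two-sided binomial test (Hits ~ Binomial(iterations, 1/2), Bonferroni
#' adjusted across candidates by default) confirms candidates with
#' significantly more hits than chance and rejects those with significantly
#' fewer; rejected candidates leave the active set. Candidates still
#' undecided at `max_iter` are tentative; optionally these are resolved by
#' comparing their median importance across iterations with the median
#' best-shadow importance.
#'
#' Decisions are invariant to candidate column order (columns are processed
#' in a fixed name order internally) and deterministic given `seed`.
#'
#' @param design A `design_matrix` from [encode_predictors()]. The forced
#'   covariate is not a candidate.
#' @param num_trees Trees per forest (default 500).
#' @param max_iter Maximum iterations (default 100).
#' @param alpha Two-sided binomial test level (default 0.01).
#' @param mc_adjust Bonferroni-adjust the binomial p-values across
#'   candidates (default TRUE).
#' @param two_shadow Use the reduced two-shadow-variable comparison instead
#'   of the shadow-copy-per-candidate loop (default FALSE).
#' @param resolve_tentative Resolve leftover tentative candidates by the
#'   median-importance rule (default FALSE).
#' @param seed Integer seed.
#' @return A `selection_result`: method `"boruta"`, per-candidate
#'   `decisions` (`"confirmed"`, `"tentative"`, `"rejected"`), `weights`
#'   (mean importance across the iterations each candidate was active),
#'   `selected` (confirmed + tentative), `hyperparameters`.
#' @export
boruta_select <- function(design, num_trees = 500, max_iter = 100,
                          alpha = 0.01, mc_adjust = TRUE, two_shadow = FALSE,
                          resolve_tentative = FALSE, seed = 1L) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(design$predictor_names) < 2)
    stop("need at least 2 candidate predictors", call. = FALSE)
  y <- design$outcome
  if (sd(y) == 0)
    stop("degenerate outcome: outcome is constant", call. = FALSE)

  ord <- order(design$predictor_names)            # fixed name order
  x_all <- design$values[, design$predictor_names[ord], drop = FALSE]
  cand <- colnames(x_all)
  status <- setNames(rep("tentative", length(cand)), cand)
  hits <- setNames(integer(length(cand)), cand)
  iters <- setNames(integer(length(cand)), cand)
  imp_hist <- setNames(vector("list", length(cand)), cand)
  shadow_max_hist <- numeric(0)

  set.seed(child_seed(seed, "boruta"))
  for (iter in seq_len(max_iter)) {
    undecided <- cand[status == "tentative"]
    if (!length(undecided)) break
    # rejected attributes leave the forest; confirmed ones stay in so that
    # chance correlations of the remaining noise stay conditionally unimportant
    kept <- cand[status != "rejected"]
    aug <- boruta_augment(x_all[, kept, drop = FALSE], two_shadow)
    fit <- ranger::ranger(
      x = aug, y = y, num.trees = num_trees, importance = "permutation",
      seed = child_seed(seed, paste0("forest", iter)), num.threads = 1)
    imp <- fit$variable.importance
    shadow_imp <- imp[grepl("^shadow_", names(imp))]
    best_shadow <- max(shadow_imp)
    shadow_max_hist <- c(shadow_max_hist, best_shadow)
    hits[undecided] <- hits[undecided] + (imp[undecided] > best_shadow)
    iters[undecided] <- iters[undecided] + 1L
    for (a in kept) imp_hist[[a]] <- c(imp_hist[[a]], imp[[a]])

    # two-sided binomial decision at level alpha
    p_hi <- pbinom(hits[undecided] - 1L, iters[undecided], 0.5,
                   lower.tail = FALSE)
    p_lo <- pbinom(hits[undecided], iters[undecided], 0.5)
    if (mc_adjust) {
      k <- length(cand)
      p_hi <- pmin(1, p_hi * k)
      p_lo <- pmin(1, p_lo * k)
    }
    status[undecided[p_hi < alpha]] <- "confirmed"
    status[undecided[p_lo < alpha]] <- "rejected"
  }

  if (resolve_tentative && any(status == "tentative")) {
    med_shadow <- stats::median(shadow_max_hist)
    for (a in cand[status == "tentative"]) {
      status[a] <- if (stats::median(imp_hist[[a]]) > med_shadow)
        "confirmed" else "rejected"
    }
  }

  weights <- vapply(imp_hist, function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))
  # back to the design's original column order
  orig <- design$predictor_names
  new_selection_result(
    method = "boruta",
    decisions = status[orig],
    weights = weights[orig],
    selected = orig[status[orig] %in% c("confirmed", "tentative")],
    hyperparameters = list(num_trees = num_trees, max_iter = max_iter,
                           alpha = alpha, mc_adjust = mc_adjust,
                           two_shadow = two_shadow,
                           resolve_tentative = resolve_tentative,
                           iterations_run = max(iters), seed = seed))
}

#' Elastic-net variable selection
#'
#' Fits the elastic-net penalized linear model (mixing parameter
#' `alpha_mix`, default 0.5) over a lambda path, choosing lambda by K-fold
#' cross-validation. The selected set is the candidates with nonzero
#' coefficient at the chosen lambda (`"1se"` by default, favouring sparse
#' models; `"min"` for the CV-minimizing lambda); the weights are those
#' penalized coefficients. Fold assignment is deterministic given `seed`
#' and invariant to candidate column order.
#'
#' @param design A `design_matrix`.
#' @param alpha_mix Elastic-net mixing parameter in `[0, 1]` (1 = lasso).
#' @param nfolds CV folds (default 10).
#' @param lambda_rule `"1se"` or `"min"`.
#' @param seed Integer seed.
#' @return A `selection_result` with method `"elastic_net"`, decisions
#'   `"selected"`/`"dropped"`, weights = penalized coefficients at the
#'   chosen lambda.
#' @export
elastic_net_select <- function(design, alpha_mix = 0.5, nfolds = 10,
                               lambda_rule = c("1se", "min"), seed = 1L) {
  stopifnot(inherits(design, "design_matrix"))
  lambda_rule <- match.arg(lambda_rule)
  if (length(design$predictor_names) < 2)
    stop("need at least 2 candidate predictors", call. = FALSE)
  n <- nrow(design$values)
  if (n < nfolds)
    stop("fold-configuration error: n (", n, ") < folds (", nfolds, ")",
         call. = FALSE)

  ord <- order(design$predictor_names)
  x <- design$values[, design$predictor_names[ord], drop = FALSE]
  y <- design$outcome
  set.seed(child_seed(seed, "enet_folds"))
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha_mix, foldid = foldid,
                          family = "gaussian")
  lam <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.vector(coef(cv, s = lam))[-1]
  names(beta) <- colnames(x)

  orig <- design$predictor_names
  beta <- beta[orig]
  decisions <- ifelse(beta != 0, "selected", "dropped")
  names(decisions) <- orig
  new_selection_result(
    method = "elastic_net",
    decisions = decisions,
    weights = beta,
    selected = orig[beta != 0],
    hyperparameters = list(alpha_mix = alpha_mix, nfolds = nfolds,
                           lambda_rule = lambda_rule, lambda = lam,
                           seed = seed))
}

new_selection_result <- function(method, decisions, weights, selected,
                                 hyperparameters) {
  structure(list(method = method, decisions = decisions, weights = weights,
                 selected = selected, hyperparameters = hyperparameters),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Variable selection (%s): %d of %d candidates selected\n",
              x$method, length(x$selected), length(x$decisions)))
  df <- data.frame(predictor = names(x$decisions),
                   decision = unname(x$decisions),
                   weight = round(unname(x$weights), 4))
  print(df[order(-abs(df$weight)), ], row.names = FALSE)
  invisible(x)
}
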