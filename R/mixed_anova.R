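#' Two-group mixed (split-plot) repeated-measures ANOVA
#'
#' Classical split-plot decomposition for a between-subjects factor with two
#' levels (optimal / non-optimal receipt) crossed with k within-subject time
#' points. Subjects missing any time point are excluded listwise (logged).
#'
#' Between-subjects stratum: one-way ANOVA on subject means (times k), F =
#' MS_group / MS_subjects-within-group. Within-subject stratum uses the
#' weighted-means decomposition, which is exactly additive for unbalanced
#' groups: SS_time from the weighted time means, SS_interaction from the
#' group-by-time cell means, and the within-subject error as the remainder;
#' under equal group sizes it coincides with the usual Type III table.
#'
#' Sphericity is assessed on the pooled within-group covariance of
#' orthonormalized contrast scores C: Mauchly's W = det(C) /
#' (tr(C)/(k-1))^(k-1) with the standard Box chi-square approximation, and
#' Greenhouse-Geisser epsilon = tr(C)^2 / ((k-1) tr(C^2)). Within-effect
#' degrees of freedom and p-values are Greenhouse-Geisser corrected; partial
#' eta squared is SS_effect / (SS_effect + SS_error) per stratum.
#'
#' @param data Long-format data frame.
#' @param subject,group,time,score Column names (defaults `"subject"`,
#'   `"group"`, `"time"`, `"score"`).
#' @param time_levels Optional explicit ordering of the time levels.
#' @return A `mixed_anova_result` list: between (`f_between`, `df_between`,
#'   `df_between_error`, `p_between`, `partial_eta2_between`), sphericity
#'   (`mauchly_w`, `mauchly_chi2`, `mauchly_df`, `mauchly_p`, `gg_epsilon`),
#'   within (`f_time`, `df_time_gg`, `df_error_gg`, `p_time`,
#'   `partial_eta2_time`, `f_interaction`, `p_interaction`,
#'   `partial_eta2_interaction`), the full `ss` table and counts.
#' @export
mixed_anova <- function(data, subject = "subject", group = "group",
                        time = "time", score = "score",
                        time_levels = NULL) {
  d <- data.frame(subject = as.character(data[[subject]]),
                  group = as.character(data[[group]]),
                  time = as.character(data[[time]]),
                  score = as.numeric(data[[score]]),
                  stringsAsFactors = FALSE)
  if (is.null(time_levels)) time_levels <- unique(d$time)
  k <- length(time_levels)
  if (k < 2) stop("need at least 2 time levels", call. = FALSE)

  wide <- stats::reshape(d, idvar = c("subject", "group"),
                         timevar = "time", direction = "wide")
  score_cols <- paste0("score.", time_levels)
  complete <- complete.cases(wide[score_cols])
  if (any(!complete))
    message(sprintf("mixed_anova: %d incomplete subject(s) excluded listwise",
                    sum(!complete)))
  wide <- wide[complete, , drop = FALSE]
  glev <- sort(unique(wide$group))
  if (length(glev) != 2)
    stop("group must have exactly 2 levels", call. = FALSE)
  n_g <- table(factor(wide$group, levels = glev))
  if (any(n_g < 2))
    stop("need at least 2 complete subjects per group", call. = FALSE)

  Y <- as.matrix(wide[score_cols])
  n <- nrow(Y)
  g <- 2L
  grp <- factor(wide$group, levels = glev)

  # between-subjects stratum: one-way ANOVA on subject means
  subj_means <- rowMeans(Y)
  gm <- mean(Y)
  grp_means <- tapply(subj_means, grp, mean)
  ss_group <- k * sum(n_g * (grp_means - gm)^2)
  ss_subj <- k * sum((subj_means - grp_means[grp])^2)
  df_group <- g - 1L
  df_subj <- n - g
  f_between <- (ss_group / df_group) / (ss_subj / df_subj)

  # within-subject stratum: weighted-means cell decomposition
  cell <- apply(Y, 2, function(col) tapply(col, grp, mean))  # g x k
  t_means <- colSums(cell * as.vector(n_g)) / n
  ss_time <- n * sum((t_means - gm)^2)
  int_dev <- sweep(sweep(cell, 1, grp_means), 2, t_means) + gm
  ss_int <- sum(as.vector(n_g) * int_dev^2)
  ss_within_total <- sum((Y - subj_means)^2)
  ss_cells <- sum(as.vector(n_g) * sweep(cell, 1, grp_means)^2)
  ss_werr <- ss_within_total - ss_cells
  df_time <- k - 1L
  df_int <- (g - 1L) * (k - 1L)
  df_werr <- (n - g) * (k - 1L)

  # sphericity on pooled within-group covariance of contrast scores
  Mc <- contr.poly(k)                      # orthonormal, orthogonal to 1
  Z <- Y %*% Mc
  z_group_means <- rowsum(Z, grp) / as.vector(n_g)
  Zc <- Z - z_group_means[as.integer(grp), , drop = FALSE]
  S <- crossprod(Zc) / (n - g)
  p <- k - 1L
  gg_epsilon <- sum(diag(S))^2 / (p * sum(S * S))
  gg_epsilon <- min(1, max(1 / p, gg_epsilon))
  if (p > 1) {
    W <- det(S) / (sum(diag(S)) / p)^p
    W <- min(1, max(W, .Machine$double.xmin))
    box <- (2 * p^2 + p + 2) / (6 * p)
    mauchly_chi2 <- -((n - g) - box) * log(W)
    mauchly_df <- as.integer(p * (p + 1) / 2 - 1)
    mauchly_p <- pchisq(mauchly_chi2, mauchly_df, lower.tail = FALSE)
  } else {
    # k = 2: a single contrast, sphericity holds trivially
    W <- 1; mauchly_chi2 <- 0; mauchly_df <- 0L; mauchly_p <- 1
    gg_epsilon <- 1
  }

  f_time <- (ss_time / df_time) / (ss_werr / df_werr)
  f_int <- (ss_int / df_int) / (ss_werr / df_werr)

  structure(list(
    n = n, k = k, groups = glev, n_per_group = as.vector(n_g),
    f_between = f_between, df_between = df_group,
    df_between_error = df_subj,
    p_between = pf(f_between, df_group, df_subj, lower.tail = FALSE),
    partial_eta2_between = ss_group / (ss_group + ss_subj),
    mauchly_w = W, mauchly_chi2 = mauchly_chi2, mauchly_df = mauchly_df,
    mauchly_p = mauchly_p,
    gg_epsilon = gg_epsilon,
    f_time = f_time,
    df_time_gg = gg_epsilon * df_time,
    df_error_gg = gg_epsilon * df_werr,
    p_time = pf(f_time, gg_epsilon * df_time, gg_epsilon * df_werr,
                lower.tail = FALSE),
    partial_eta2_time = ss_time / (ss_time + ss_werr),
    f_interaction = f_int,
    df_interaction_gg = gg_epsilon * df_int,
    p_interaction = pf(f_int, gg_epsilon * df_int, gg_epsilon * df_werr,
                       lower.tail = FALSE),
    partial_eta2_interaction = ss_int / (ss_int + ss_werr),
    ss = data.frame(
      term = c("group", "subjects_within_group", "time",
               "group_x_time", "within_error"),
      ss = c(ss_group, ss_subj, ss_time, ss_int, ss_werr),
      df = c(df_group, df_subj, df_time, df_int, df_werr))
  ), class = "mixed_anova_result")
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA: %d subjects (%s: %d / %d), %d time points\n",
              x$n, paste(x$groups, collapse = " vs "),
              x$n_per_group[1], x$n_per_group[2], x$k))
  cat(sprintf("  between  F(%d, %d) = %.3f, p = %.4g, partial eta2 = %.3f\n",
              x$df_between, x$df_between_error, x$f_between, x$p_between,
              x$partial_eta2_between))
  cat(sprintf("  Mauchly  W = %.3f, X2(%d) = %.2f, p = %.4g; GG epsilon = %.3f\n",
              x$mauchly_w, x$mauchly_df, x$mauchly_chi2, x$mauchly_p,
              x$gg_epsilon))
  cat(sprintf("  time     F(%.2f, %.2f) = %.3f, p = %.4g, partial eta2 = %.3f\n",
              x$df_time_gg, x$df_error_gg, x$f_time, x$p_time,
              x$partial_eta2_time))
  cat(sprintf("  group:time F(%.2f, %.2f) = %.3f, p = %.4g, partial eta2 = %.3f\n",
              x$df_interaction_gg, x$df_error_gg, x$f_interaction,
              x$p_interaction, x$partial_eta2_interaction))
  invisible(x)
}

#' Read a long-format scores table from CSV
#'
#' Expects columns `subject`, `group`, `time`, `score` (extra columns kept).
#' @param path CSV path.
#' @return Data frame suitable for [mixed_anova()].
#' @export
read_anova_long <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "time", "score")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("long CSV lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d
}

#' Read a 2x2 contingency table from JSON
#'
#' JSON is a 2x2 array of counts, e.g. `[[47, 84], [13, 65]]`.
#' @param path JSON path.
#' @return 2x2 integer matrix.
#' @export
read_table_json <- function(path) {
  m <- jsonlite::fromJSON(path)
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2)))
    stop("expected a 2x2 array of counts", call. = FALSE)
  m
}

#' Write an analysis result to JSON with intermediate fields
#'
#' Serializes any of the package's result objects (contingency, t-summary,
#' mixed ANOVA, report bundles) with all intermediate SS/df fields intact.
#' @param result A result object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  x <- unclass(result)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, dataframe = "rows")
  invisible(path)
}
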