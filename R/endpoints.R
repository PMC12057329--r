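#' Reliable and clinically significant improvement rule
#'
#' RCSI on the GAD-7 requires a reliable improvement of at least
#' `reliable_change` points (default 4) AND an end score strictly below the
#' clinical caseness cut-off (default 8).
#'
#' @param reliable_change Minimum baseline-minus-end change (positive
#'   integer, GAD-7 points).
#' @param caseness_cutoff End score must be strictly below this (positive
#'   integer).
#' @return An `rcsi_rule` list.
#' @export
rcsi_rule <- function(reliable_change = 4L, caseness_cutoff = 8L) {
  stopifnot(reliable_change > 0, caseness_cutoff > 0,
            reliable_change == round(reliable_change),
            caseness_cutoff == round(caseness_cutoff))
  structure(list(reliable_change = as.integer(reliable_change),
                 caseness_cutoff = as.integer(caseness_cutoff)),
            class = "rcsi_rule")
}

#' Flag reliable and clinically significant improvement
#'
#' @param baseline,end GAD-7 scores (vectors, within 0-21).
#' @param rule An [rcsi_rule()].
#' @return Logical vector: TRUE iff `(baseline - end) >= reliable_change`
#'   and `end < caseness_cutoff`.
#' @export
rcsi_flag <- function(baseline, end, rule = rcsi_rule()) {
  stopifnot(length(baseline) == length(end))
  rng <- .scale_ranges$gad7
  ok <- stats::na.omit(c(baseline, end))
  if (any(ok < rng[1] | ok > rng[2]))
    stop("GAD-7 scores must lie in [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  (baseline - end) >= rule$reliable_change & end < rule$caseness_cutoff
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction), df = 1,
#' with the expected counts retained for auditability.
#'
#' @param table 2x2 matrix of non-negative counts (rows = groups, columns =
#'   event/no-event).
#' @return A `contingency_result`: list with `table`, `chi2`, `df`,
#'   `p_value`, `expected`.
#' @export
pearson_chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("undefined test: zero marginal total", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(table = table,
                 chi2 = unname(ct$statistic),
                 df = 1L,
                 p_value = unname(ct$p.value),
                 expected = ct$expected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square (no continuity correction): X2(1, N = %d) = %.2f, p = %.4g\n",
              sum(x$table), x$chi2, x$p_value))
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product odds ratio oriented as row-2 event odds divided by row-1
#' event odds. With rows ordered (optimal, non-optimal) and the event in
#' column 1, this is the non-optimal vs optimal odds ratio: values below 1
#' mean the non-optimal group fared worse. A zero cell raises an error by
#' default; the Haldane-Anscombe policy adds 0.5 to every cell instead.
#'
#' @param table 2x2 count matrix.
#' @param zero_cell_policy `"error"` (default) or `"haldane"`.
#' @return The odds ratio (scalar), with attribute `orientation`.
#' @export
odds_ratio_2x2 <- function(table, zero_cell_policy = c("error", "haldane")) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(table == 0)) {
    if (zero_cell_policy == "error")
      stop("zero cell: odds ratio undefined (use zero_cell_policy = \"haldane\")",
           call. = FALSE)
    table <- table + 0.5
  }
  or <- (table[2, 1] / table[2, 2]) / (table[1, 1] / table[1, 2])
  attr(or, "orientation") <- "row2 event odds / row1 event odds"
  or
}

#' Pooled-variance two-sample t test from group summaries
#'
#' Reconstructs the classical equal-variance two-sample t statistic from
#' printed means, SDs and group sizes. Direction is group 2 minus group 1.
#'
#' @param m1,sd1,n1 Mean, SD, size of group 1.
#' @param m2,sd2,n2 Mean, SD, size of group 2.
#' @return A `t_summary_result`: list with `t`, `df` (= n1 + n2 - 2),
#'   `p_value` (two-sided), `direction`.
#' @export
pooled_two_sample_t <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  structure(list(t = t, df = as.integer(df),
                 p_value = 2 * pt(-abs(t), df),
                 direction = "group2 - group1"),
            class = "t_summary_result")
}

#' @export
print.t_summary_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.2f, p = %.4g  (%s)\n",
              x$df, x$t, x$p_value, x$direction))
  invisible(x)
}

#' Reconstruct integer counts from printed percentages
#'
#' Each count is `round(n * pct / 100)` with ties rounded half-up (so 2.5
#' becomes 3), matching how published percentages are back-converted. When
#' the percentages are meant to exhaust the total, any mismatch between the
#' reconstructed sum and `n` is reported via attribute `total_mismatch`.
#'
#' @param n Total count.
#' @param percentages Numeric vector in `[0, 100]`.
#' @return Integer vector of counts.
#' @export
counts_from_percentages <- function(n, percentages) {
  stopifnot(all(percentages >= 0), all(percentages <= 100))
  counts <- as.integer(floor(n * percentages / 100 + 0.5))
  if (isTRUE(all.equal(sum(percentages), 100)) && sum(counts) != n)
    attr(counts, "total_mismatch") <- sum(counts) - n
  counts
}

#' RCSI endpoint comparison between optimal and non-optimal groups
#'
#' Builds the 2x2 table (rows optimal / non-optimal, columns RCSI yes/no),
#' and returns the chi-square test, the odds ratio (non-optimal vs optimal
#' orientation) and the per-group rates. Patients without an indicated arm
#' are excluded.
#'
#' @param optimal Logical vector (TRUE = received indicated arm; NA =
#'   no indication).
#' @param rcsi Logical vector of RCSI flags.
#' @param zero_cell_policy Passed to [odds_ratio_2x2()].
#' @return List with `table`, `chi2` (a `contingency_result`),
#'   `odds_ratio`, `rates` (named: optimal, non_optimal).
#' @export
rcsi_endpoint <- function(optimal, rcsi, zero_cell_policy = "haldane") {
  stopifnot(length(optimal) == length(rcsi))
  keep <- !is.na(optimal) & !is.na(rcsi)
  optimal <- optimal[keep]; rcsi <- rcsi[keep]
  tab <- rbind(optimal = c(sum(optimal & rcsi), sum(optimal & !rcsi)),
               non_optimal = c(sum(!optimal & rcsi), sum(!optimal & !rcsi)))
  colnames(tab) <- c("rcsi", "no_rcsi")
  list(table = tab,
       chi2 = pearson_chi2_2x2(tab),
       odds_ratio = odds_ratio_2x2(tab, zero_cell_policy),
       rates = c(optimal = tab[1, 1] / sum(tab[1, ]),
                 non_optimal = tab[2, 1] / sum(tab[2, ])))
}
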