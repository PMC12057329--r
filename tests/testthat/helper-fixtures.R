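# Shared fixtures and independent oracles for the test suite.

# Build a design_matrix directly from numeric pieces, bypassing the encoder,
# for unit tests of the modelling operations.
toy_design <- function(x, y, forced = NULL, arm = "CAT",
                       forced_name = "gad7_baseline") {
  n <- nrow(x)
  if (ncol(x) > 0 && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(
    values = x,
    predictor_names = colnames(x),
    encoding_meta = data.frame(name = c(colnames(x), forced_name),
                               type = "continuous",
                               center = 0, scale = 1,
                               positive_level = NA_character_),
    outcome = y,
    outcome_name = "gad7_post",
    forced_covariate = forced,
    forced_name = if (is.null(forced)) NULL else forced_name,
    arm = rep(arm, n),
    patient_id = sprintf("P%04d", seq_len(n))
  ), class = "design_matrix")
}

# Random regression design for parameterized cases.
random_design <- function(n, p, seed, beta = NULL, noise_sd = 1,
                          forced_beta = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  forced <- rnorm(n)
  if (is.null(beta)) beta <- rnorm(p)
  y <- as.vector(x %*% beta) + forced_beta * forced + rnorm(n, 0, noise_sd)
  toy_design(x, y, forced = forced)
}

# Brute-force LOOCV oracle: literally refit n separate regressions.
loocv_brute_force <- function(design, selected) {
  mm <- cbind(1, design$values[, selected, drop = FALSE],
              design$forced_covariate)
  y <- design$outcome
  vapply(seq_len(nrow(mm)), function(i) {
    fit <- lm.fit(mm[-i, , drop = FALSE], y[-i])
    sum(mm[i, ] * fit$coefficients)
  }, numeric(1))
}

# First-principles split-plot sums of squares from cell means, written as
# plain loops over the long table; independent of the package's linear
# algebra path.
anova_ss_oracle <- function(long) {
  subjects <- unique(long$subject)
  times <- unique(long$time)
  k <- length(times)
  gm <- mean(long$score)
  subj_mean <- sapply(subjects, function(s) mean(long$score[long$subject == s]))
  subj_group <- sapply(subjects, function(s) long$group[long$subject == s][1])
  groups <- unique(subj_group)
  grp_mean <- sapply(groups, function(g) mean(subj_mean[subj_group == g]))
  n_g <- sapply(groups, function(g) sum(subj_group == g))
  n <- length(subjects)

  ss_group <- k * sum(n_g * (grp_mean - gm)^2)
  ss_subj <- k * sum((subj_mean - grp_mean[match(subj_group, groups)])^2)

  cell <- outer(groups, times, Vectorize(function(g, t)
    mean(long$score[long$group == g & long$time == t])))
  t_mean <- sapply(seq_along(times), function(j) sum(n_g * cell[, j]) / n)
  ss_time <- n * sum((t_mean - gm)^2)
  ss_int <- 0
  for (gi in seq_along(groups)) for (j in seq_along(times))
    ss_int <- ss_int + n_g[gi] *
      (cell[gi, j] - grp_mean[gi] - t_mean[j] + gm)^2
  ss_werr <- 0
  for (s in subjects) for (t in times) {
    y <- long$score[long$subject == s & long$time == t]
    gi <- match(subj_group[match(s, subjects)], groups)
    j <- match(t, times)
    ss_werr <- ss_werr +
      (y - subj_mean[match(s, subjects)] - cell[gi, j] + grp_mean[gi])^2
  }
  list(group = unname(ss_group), subj = unname(ss_subj),
       time = unname(ss_time), interaction = unname(ss_int),
       within_error = unname(ss_werr),
       total = sum((long$score - gm)^2))
}

# Long-format repeated-measures table from a subjects x times score matrix.
make_long <- function(scores, group) {
  k <- ncol(scores)
  n <- nrow(scores)
  data.frame(
    subject = rep(sprintf("S%03d", seq_len(n)), k),
    group = rep(group, k),
    time = rep(paste0("t", seq_len(k)), each = n),
    score = as.vector(scores))
}

# Small complete trial dataset built by hand (no generator) for preprocess
# unit tests.
tiny_trial <- function(n = 12, seed = 1, missing_cells = 0) {
  set.seed(seed)
  d <- data.frame(
    patient_id = sprintf("P%04d", 1:n),
    arm = rep(c("CAT", "CBT"), length.out = n),
    allocation = rep(c("preference", "preference", "randomized"),
                     length.out = n),
    sessions = rep(2:7, length.out = n),
    age = round(rnorm(n, 36, 12), 1),
    unemployed = rbinom(n, 1, 0.3),
    phq9_baseline = pmin(27, pmax(0, round(rnorm(n, 14, 5)))),
    gad7_baseline = pmin(21, pmax(0, round(rnorm(n, 13, 4)))),
    gad7_post = pmin(21, pmax(0, round(rnorm(n, 9, 4)))),
    gad7_followup = pmin(21, pmax(0, round(rnorm(n, 8, 4)))),
    stringsAsFactors = FALSE)
  if (missing_cells > 0) {
    cols <- c("age", "unemployed", "phq9_baseline")
    for (i in seq_len(missing_cells)) {
      d[sample(n, 1), sample(cols, 1)] <- NA
    }
  }
  structure(d, class = c("trial_dataset", "data.frame"))
}
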