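test_that("episode filter retains exactly the records meeting the criterion", {
  d <- tiny_trial(n = 8)
  d$sessions <- c(0, 1, 2, 3, 0, 2, 5, 1)
  expect_message(out <- apply_episode_filter(d), "4 retained, 4 excluded")
  expect_equal(nrow(out), 4)
  expect_true(all(out$sessions >= 2))

  all_in <- tiny_trial(n = 6)
  all_in$sessions <- rep(3, 6)
  expect_equal(nrow(suppressMessages(apply_episode_filter(all_in))), 6)

  none <- tiny_trial(n = 3)
  none$sessions <- c(0, 1, 1)
  expect_error(suppressMessages(apply_episode_filter(none)), "empty dataset")
})

test_that("a 271-patient sample with 62 sub-episode cases filters to 209", {
  d <- tiny_trial(n = 271, seed = 10)
  d$sessions <- c(rep(1, 62), rep(4, 209))[sample.int(271)]
  out <- suppressMessages(apply_episode_filter(d))
  expect_equal(nrow(out), 209)
})

test_that("missingness screen drops strictly above the threshold only", {
  d <- tiny_trial(n = 50, seed = 3)
  d$marital_status <- ifelse(seq_len(50) <= 7, "married", NA)  # 86% missing
  d$half_missing <- ifelse(seq_len(50) <= 25, 1, NA)           # exactly 50%
  scr <- suppressMessages(screen_missingness(d, 0.5))
  expect_equal(scr$dropped, "marital_status")
  expect_false("marital_status" %in% names(scr$dataset))
  expect_true("half_missing" %in% names(scr$dataset))   # at threshold: kept
  expect_true("age" %in% names(scr$dataset))            # 0% missing: kept
})

test_that("imputation is deterministic, complete, and leaves observed cells alone", {
  d <- tiny_trial(n = 40, seed = 4, missing_cells = 15)
  expect_true(anyNA(d))
  imp1 <- impute_rf(d, seed = 11)
  imp2 <- impute_rf(d, seed = 11)
  expect_identical(imp1, imp2)
  expect_false(anyNA(imp1[c("age", "unemployed", "phq9_baseline")]))
  obs <- !is.na(d$age)
  expect_equal(imp1$age[obs], d$age[obs])
  obs <- !is.na(d$phq9_baseline)
  expect_equal(imp1$phq9_baseline[obs], d$phq9_baseline[obs])

  # binary column stays binary after imputation
  expect_true(all(imp1$unemployed %in% c(0, 1)))

  # no missing cells: identity
  complete <- tiny_trial(n = 20, seed = 5)
  expect_identical(impute_rf(complete, seed = 1), complete)

  # entirely missing variable is unimputable
  broken <- tiny_trial(n = 10, seed = 6)
  broken$age <- NA_real_
  expect_error(impute_rf(broken, seed = 1), "unimputable")
})

test_that("random-forest imputation beats mean imputation on correlated data", {
  set.seed(11)
  n <- 200
  x1 <- rnorm(n); x2 <- 0.9 * x1 + rnorm(n, 0, 0.3)
  x3 <- -0.8 * x1 + rnorm(n, 0, 0.4)
  d <- data.frame(patient_id = sprintf("P%04d", 1:n), arm = "CAT",
                  allocation = "preference", sessions = 4,
                  v1 = x1, v2 = x2, v3 = x3,
                  gad7_baseline = 10, gad7_post = 8, gad7_followup = 8)
  class(d) <- c("trial_dataset", "data.frame")
  truth <- d$v2
  mask <- sample(n, round(0.2 * n))            # MCAR 20%
  d$v2[mask] <- NA
  imp <- impute_rf(d, seed = 11)
  rmse_rf <- sqrt(mean((imp$v2[mask] - truth[mask])^2))
  rmse_mean <- sqrt(mean((mean(d$v2, na.rm = TRUE) - truth[mask])^2))
  expect_lt(rmse_rf, rmse_mean)
})

test_that("encoding standardizes, dummy codes to +/-0.5, and records metadata", {
  d <- tiny_trial(n = 30, seed = 7)
  design <- encode_predictors(d)
  # continuous columns: mean 0, sd 1
  for (cn in c("age", "phq9_baseline")) {
    expect_equal(mean(design$values[, cn]), 0, tolerance = 1e-9)
    expect_equal(sd(design$values[, cn]), 1, tolerance = 1e-9)
  }
  expect_true(all(design$values[, "unemployed"] %in% c(-0.5, 0.5)))
  # the alphabetically later level codes +0.5
  meta <- design$encoding_meta
  expect_equal(meta$positive_level[meta$name == "unemployed"], "1")
  # forced covariate excluded from candidates but encoded
  expect_false("gad7_baseline" %in% design$predictor_names)
  expect_equal(mean(design$forced_covariate), 0, tolerance = 1e-9)
  expect_false(anyNA(design$values))
})

test_that("constant predictors are dropped with a warning", {
  d <- tiny_trial(n = 20, seed = 8)
  d$constant <- 5
  expect_warning(design <- encode_predictors(d), "zero-variance.*constant")
  expect_false("constant" %in% design$predictor_names)
  expect_true("constant" %in%
                design$encoding_meta$name[design$encoding_meta$type == "dropped"])
})

test_that("re-applying stored encoding reproduces the design matrix exactly", {
  d <- tiny_trial(n = 25, seed = 9)
  design <- encode_predictors(d)
  enc <- apply_encoding(d, design$encoding_meta)
  expect_equal(enc[, design$predictor_names], design$values)
  expect_equal(enc[, "gad7_baseline"], design$forced_covariate)
})

test_that("per-arm encoding is independent across arms", {
  d <- tiny_trial(n = 40, seed = 12)
  cat_arm <- d[d$arm == "CAT", ]; class(cat_arm) <- class(d)
  cbt_arm <- d[d$arm == "CBT", ]; class(cbt_arm) <- class(d)
  dc <- encode_predictors(cat_arm)
  db <- encode_predictors(cbt_arm)
  mc <- dc$encoding_meta; mb <- db$encoding_meta
  # each arm standardizes by its own sample moments
  expect_false(isTRUE(all.equal(mc$center[mc$name == "age"],
                                mb$center[mb$name == "age"])))
  expect_equal(mean(dc$values[, "age"]), 0, tolerance = 1e-9)
  expect_equal(mean(db$values[, "age"]), 0, tolerance = 1e-9)
})

test_that("multi-level categoricals collapse to documented binaries", {
  d <- tiny_trial(n = 30, seed = 13)
  d$employment <- sample(c("employed", "unemployed", "student", "retired"),
                         30, replace = TRUE)
  design <- encode_predictors(d, collapse = list(employment = "unemployed"))
  expect_true(all(design$values[, "employment"] %in% c(-0.5, 0.5)))
  expect_equal(design$values[, "employment"],
               ifelse(d$employment == "unemployed", 0.5, -0.5))
})
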