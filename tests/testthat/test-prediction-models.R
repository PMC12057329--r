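test_that("intercept-only LOOCV predictions are the leave-one-out means", {
  d <- toy_design(matrix(numeric(0), 3, 0), y = c(1, 2, 3))
  expect_equal(loocv_predictions(d, character(0)), c(2.5, 2.0, 1.5))
})

test_that("LOOCV equals the brute-force refit loop on random instances", {
  for (seed in 1:20) {
    n <- sample(15:50, 1)
    p <- sample(1:4, 1)
    design <- random_design(n, p, seed = seed, noise_sd = 1, forced_beta = 0.5)
    sel <- design$predictor_names
    expect_equal(loocv_predictions(design, sel),
                 loocv_brute_force(design, sel),
                 tolerance = 1e-10)
  }
})

test_that("noiseless linear data is predicted exactly and rank problems error", {
  design <- random_design(30, 3, seed = 2, noise_sd = 0, forced_beta = 1)
  pred <- loocv_predictions(design, design$predictor_names)
  expect_equal(pred, design$outcome, tolerance = 1e-8)

  # duplicated column -> rank deficient
  x <- design$values
  x2 <- cbind(x, dup = x[, 1])
  bad <- toy_design(x2, design$outcome, forced = design$forced_covariate)
  expect_error(loocv_predictions(bad, bad$predictor_names), "singular")
  expect_error(loocv_predictions(design, c("x1", "nope")), "unknown predictors")
})

test_that("cv_metrics matches direct arithmetic and its invariants", {
  m <- cv_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-4)   # 0.5774
  expect_equal(m$mae, 1 / 3, tolerance = 1e-4)          # 0.3333
  expect_equal(m$r, 0.9820, tolerance = 1e-4)
  expect_equal(m$r2, 1 - 1 / (14 / 3), tolerance = 1e-4)  # 0.7857
  expect_equal(m$r2_pearson, m$r^2)

  exact <- cv_metrics(c(4, 5, 6), c(4, 5, 6))
  expect_equal(exact$rmse, 0); expect_equal(exact$mae, 0)
  expect_equal(exact$r, 1); expect_equal(exact$r2, 1)

  shifted <- cv_metrics(c(1, 2, 3) + 2.5, c(1, 2, 3))
  expect_equal(shifted$rmse, 2.5)
  expect_equal(shifted$mae, 2.5)
  expect_equal(shifted$r, 1)

  expect_gte(m$rmse, m$mae)
  expect_error(cv_metrics(c(1, 2, 3), c(2, 2, 2)), "constant")
})

test_that("preferred-method rule: dominance, congruence tie-break, rmse priority", {
  mk <- function(rmse, mae, r)
    structure(list(rmse = rmse, mae = mae, r = r, r2 = r^2,
                   r2_pearson = r^2, n = 100), class = "cv_metrics")
  # published pattern: elastic net dominates in one arm, exact tie in the other
  metrics <- list(
    CAT = list(boruta = mk(4.09, 3.21, 0.62),
               elastic_net = mk(4.03, 3.12, 0.64)),
    CBT = list(boruta = mk(4.50, 3.62, 0.54),
               elastic_net = mk(4.50, 3.62, 0.54)))
  ch <- select_preferred_method(metrics)
  expect_equal(unname(ch$choice["CAT"]), "elastic_net")
  expect_equal(unname(ch$choice["CBT"]), "elastic_net")  # congruence
  expect_match(paste(ch$notes, collapse = "; "), "deferring")

  # full tie everywhere -> default elastic_net
  tied <- list(CAT = list(boruta = mk(4, 3, .5), elastic_net = mk(4, 3, .5)),
               CBT = list(boruta = mk(4, 3, .5), elastic_net = mk(4, 3, .5)))
  cht <- select_preferred_method(tied)
  expect_equal(unname(cht$choice), c("elastic_net", "elastic_net"))

  # conflict: method A lower rmse, method B higher r -> rmse decides, logged
  conf <- list(CAT = list(boruta = mk(4.0, 3.3, .60),
                          elastic_net = mk(4.2, 3.1, .65)),
               CBT = list(boruta = mk(4.5, 3.6, .54),
                          elastic_net = mk(4.4, 3.5, .55)))
  chc <- select_preferred_method(conf)
  expect_equal(unname(chc$choice["CAT"]), "boruta")
  expect_match(paste(chc$notes, collapse = "; "), "RMSE")
})

test_that("final model recovers coefficients and matches the normal equations", {
  design <- random_design(30, 3, seed = 4, noise_sd = 0, forced_beta = 2)
  model <- fit_final_model(design, design$predictor_names)
  # noiseless: recovered coefficients equal generating ones
  set.seed(4)  # regenerate the betas used by random_design
  x <- matrix(rnorm(30 * 3), 30, 3); forced <- rnorm(30); beta <- rnorm(3)
  expect_equal(unname(model$coefficients),
               c(0, beta, 2), tolerance = 1e-8)

  # normal-equations oracle on a noisy 10 x 3 instance
  d2 <- random_design(10, 3, seed = 5, noise_sd = 1)
  m2 <- fit_final_model(d2, d2$predictor_names)
  mm <- cbind(1, d2$values, d2$forced_covariate)
  beta_ne <- solve(t(mm) %*% mm, t(mm) %*% d2$outcome)
  expect_equal(unname(m2$coefficients), as.vector(beta_ne), tolerance = 1e-10)

  # row permutation leaves the fit unchanged
  perm <- sample(10)
  d3 <- toy_design(d2$values[perm, ], d2$outcome[perm],
                   forced = d2$forced_covariate[perm])
  m3 <- fit_final_model(d3, d3$predictor_names)
  expect_equal(m3$coefficients, m2$coefficients, tolerance = 1e-10)
})

test_that("predict_outcome scores raw rows through the stored encoding", {
  d <- tiny_trial(n = 30, seed = 14)
  cat_arm <- d[d$arm == "CAT", ]; class(cat_arm) <- class(d)
  design <- encode_predictors(cat_arm)
  model <- fit_final_model(design, c("age", "phq9_baseline"))
  # own-arm predictions equal the full-fit fitted values
  expect_equal(predict_outcome(model, cat_arm), model$fitted, tolerance = 1e-10)
  # cross-arm rows score through the CAT arm's encoding without error
  cbt_arm <- d[d$arm == "CBT", ]
  expect_length(predict_outcome(model, cbt_arm), nrow(cbt_arm))
  # missing column -> schema error
  expect_error(predict_outcome(model, cbt_arm[, -5]), "schema error|missing")
})

test_that("predictions are invariant to affine rescaling when meta travels along", {
  d <- tiny_trial(n = 24, seed = 15)
  cat_arm <- d[d$arm == "CAT", ]; class(cat_arm) <- class(d)
  design <- encode_predictors(cat_arm)
  model <- fit_final_model(design, c("age", "phq9_baseline"))
  base_pred <- predict_outcome(model, cat_arm)

  # double the raw scale of age; re-encode; refit: same predictions on the
  # correspondingly rescaled raw inputs
  scaled <- cat_arm
  scaled$age <- scaled$age * 2
  design2 <- encode_predictors(scaled)
  model2 <- fit_final_model(design2, c("age", "phq9_baseline"))
  expect_equal(predict_outcome(model2, scaled), base_pred, tolerance = 1e-8)
})

test_that("LOOCV error is no better than in-sample error on average", {
  diffs <- vapply(1:20, function(seed) {
    design <- random_design(40, 3, seed = 100 + seed, noise_sd = 2)
    sel <- design$predictor_names
    loo <- cv_metrics(loocv_predictions(design, sel), design$outcome)
    fit <- fit_final_model(design, sel)
    ins <- cv_metrics(fit$fitted, design$outcome)
    loo$rmse - ins$rmse
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
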