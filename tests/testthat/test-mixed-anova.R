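test_that("identical groups give a null between-subjects effect", {
  set.seed(1)
  scores <- matrix(rnorm(30, 10, 3), 10, 3)
  long <- rbind(make_long(scores, "optimal"), make_long(scores, "non_optimal"))
  long$subject <- paste0(long$group, "_", long$subject)
  res <- mixed_anova(long)
  expect_equal(res$f_between, 0, tolerance = 1e-20)
  expect_equal(res$partial_eta2_between, 0, tolerance = 1e-20)
})

test_that("with two time levels epsilon is exactly 1 and Mauchly is trivial", {
  set.seed(2)
  scores <- matrix(rnorm(40, 10, 3), 20, 2)
  long <- make_long(scores, rep(c("a", "b"), each = 10))
  res <- mixed_anova(long)
  expect_identical(res$gg_epsilon, 1)
  expect_equal(res$mauchly_w, 1)
  expect_equal(res$mauchly_df, 0L)
})

test_that("sums of squares equal a first-principles oracle on a small balanced table", {
  set.seed(3)
  scores <- matrix(rnorm(24, 12, 4), 8, 3)
  long <- make_long(scores, rep(c("optimal", "non_optimal"), each = 4))
  res <- mixed_anova(long)
  oracle <- anova_ss_oracle(long)
  ss <- setNames(res$ss$ss, res$ss$term)
  expect_equal(unname(ss["group"]), oracle$group, tolerance = 1e-10)
  expect_equal(unname(ss["subjects_within_group"]), oracle$subj,
               tolerance = 1e-10)
  expect_equal(unname(ss["time"]), oracle$time, tolerance = 1e-10)
  expect_equal(unname(ss["group_x_time"]), oracle$interaction,
               tolerance = 1e-10)
  expect_equal(unname(ss["within_error"]), oracle$within_error,
               tolerance = 1e-10)
})

test_that("the SS decomposition is additive, including unbalanced groups", {
  for (seed in 1:5) {
    set.seed(seed)
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1); k <- sample(2:4, 1)
    scores <- matrix(rnorm((n1 + n2) * k, 10, 3), n1 + n2, k)
    long <- make_long(scores, rep(c("g1", "g2"), c(n1, n2)))
    res <- mixed_anova(long)
    oracle <- anova_ss_oracle(long)
    expect_equal(sum(res$ss$ss), oracle$total, tolerance = 1e-8)
    expect_gte(res$gg_epsilon, 1 / (k - 1))
    expect_lte(res$gg_epsilon, 1)
  }
})

test_that("Mauchly test and GG epsilon match the standard implementations", {
  skip_if_not_installed("car")
  set.seed(10)
  n1 <- 14; n2 <- 9; k <- 3
  scores <- matrix(rnorm((n1 + n2) * k, 10, 3), n1 + n2, k)
  # induce non-sphericity
  scores[, 3] <- scores[, 3] * 2 + 0.8 * scores[, 1]
  grp <- rep(c("g1", "g2"), c(n1, n2))
  long <- make_long(scores, grp)
  res <- mixed_anova(long)

  idata <- data.frame(time = factor(paste0("t", 1:k)))
  mlm <- lm(scores ~ grp)
  av <- car::Anova(mlm, idata = idata, idesign = ~time, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  expect_equal(unname(res$mauchly_w),
               unname(s$sphericity.tests["time", "Test statistic"]),
               tolerance = 1e-8)
  expect_equal(unname(res$gg_epsilon),
               unname(s$pval.adjustments["time", "GG eps"]),
               tolerance = 1e-8)
  # univariate F table agrees under (near) balance is not guaranteed for
  # unbalanced Type III; check between-subjects stratum which is one-way
  expect_equal(unname(res$f_between),
               s$univariate.tests["grp", "F value"], tolerance = 1e-8)
})

test_that("balanced-design F statistics match car's univariate table", {
  skip_if_not_installed("car")
  set.seed(11)
  n <- 10; k <- 3
  scores <- matrix(rnorm(2 * n * k, 11, 4), 2 * n, k)
  grp <- rep(c("g1", "g2"), each = n)
  res <- mixed_anova(make_long(scores, grp))
  av <- car::Anova(lm(scores ~ grp, contrasts = list(grp = contr.sum)),
                   idata = data.frame(time = factor(paste0("t", 1:k))),
                   idesign = ~time, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  expect_equal(res$f_time, s$univariate.tests["time", "F value"],
               tolerance = 1e-8)
  expect_equal(res$f_interaction, s$univariate.tests["grp:time", "F value"],
               tolerance = 1e-8)
  expect_equal(res$f_between, s$univariate.tests["grp", "F value"],
               tolerance = 1e-8)
})

test_that("incomplete subjects are excluded listwise with a log message", {
  set.seed(4)
  scores <- matrix(rnorm(30, 10, 3), 10, 3)
  long <- make_long(scores, rep(c("a", "b"), each = 5))
  long <- long[!(long$subject == "S001" & long$time == "t3"), ]
  expect_message(res <- mixed_anova(long), "1 incomplete")
  expect_equal(res$n, 9)
  expect_error(mixed_anova(long[long$time == "t1", ]), "at least 2 time")
})

test_that("Mauchly rejection rate is near alpha under a spherical generator", {
  set.seed(42)
  reps <- 400
  n <- 50; k <- 3
  rejections <- vapply(seq_len(reps), function(i) {
    scores <- matrix(rnorm(n * k), n, k)       # iid: sphericity holds
    res <- suppressMessages(
      mixed_anova(make_long(scores, rep(c("a", "b"), each = n / 2))))
    res$mauchly_p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("long CSV and 2x2 JSON readers round-trip", {
  set.seed(5)
  scores <- matrix(rnorm(24, 9, 3), 8, 3)
  long <- make_long(scores, rep(c("a", "b"), each = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  back <- read_anova_long(path)
  expect_equal(back$score, long$score)

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rbind(c(47, 84), c(13, 65)), jpath)
  tab <- read_table_json(jpath)
  expect_equal(unname(tab), rbind(c(47, 84), c(13, 65)))

  out <- withr::local_tempfile(fileext = ".json")
  res <- mixed_anova(long)
  write_result_json(res, out)
  parsed <- jsonlite::fromJSON(out)
  expect_equal(parsed$f_between, res$f_between, tolerance = 1e-12)
  expect_equal(nrow(parsed$ss), 5)
})
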