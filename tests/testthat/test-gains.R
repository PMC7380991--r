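test_that("session scoring is the first-attempt percentage", {
  t0 <- as.POSIXct("2019-03-01", tz = "UTC")
  s <- toy_session("X", "control", 1, rep(TRUE, 12), t0)
  expect_equal(score_session(s), 100)
  s <- toy_session("X", "control", 1, rep(FALSE, 12), t0)
  expect_equal(score_session(s), 0)
  s <- toy_session("X", "control", 1, c(rep(TRUE, 9), rep(FALSE, 3)), t0)
  expect_equal(score_session(s), 75)
  s$completed <- FALSE
  expect_error(score_session(s), "incomplete")
})

test_that("normalized gain implements (post - pre) / (100 - pre)", {
  expect_equal(normalized_gain(50, 85), 0.7)
  expect_equal(normalized_gain(60, 60), 0)
  expect_equal(normalized_gain(60, 100), 1)
  expect_equal(normalized_gain(80, 60), -1)
  expect_true(is.na(normalized_gain(100, 100)))
  expect_error(normalized_gain(50, 120), "0, 100")
  # gain = 1 only at a perfect posttest from an imperfect pretest
  set.seed(1)
  pre <- runif(100, 0, 99)
  post <- runif(100, 0, 100)
  g <- normalized_gain(pre, post)
  expect_identical(g == 1, post == 100)
})

test_that("normalized gain is invariant to rescaling scores to [0, 1]", {
  set.seed(2)
  pre <- runif(50, 0, 95)
  post <- runif(50, 0, 100)
  g_pct <- normalized_gain(pre, post)
  g_unit <- (post / 100 - pre / 100) / (1 - pre / 100)
  expect_equal(g_pct, g_unit, tolerance = 1e-12)
})

test_that("spacing bins are half-open with a clamped one-month tail", {
  t0 <- as.POSIXct("2019-03-01 08:00:00", tz = "UTC")
  cat1 <- spacing_category(t0, t0 + 30 * 60)
  expect_equal(as.character(cat1), "<=1 hour")
  expect_equal(as.character(spacing_category(t0, t0 + 3600)), "<=1 hour")
  expect_equal(as.character(spacing_category(t0, t0 + 3601)), "<=1 day")
  expect_equal(as.character(spacing_category(t0, t0 + 5 * 86400)),
               "<=1 week")
  expect_equal(as.character(spacing_category(t0, t0 + 10 * 86400)),
               "<=1 month")
  over <- spacing_category(t0, t0 + 40 * 86400)
  expect_equal(as.character(over), "<=1 month")
  expect_true(attr(over, "clamped"))
  expect_error(spacing_category(t0, t0 - 60), "negative interval")
})

test_that("help ratio divides hints by tries", {
  t0 <- as.POSIXct("2019-03-01", tz = "UTC")
  s <- toy_session("X", "control", 2, rep(TRUE, 12), t0)
  expect_equal(help_ratio(s), 0)
  # 6 failed first attempts -> 6 hints over 18 tries
  s <- toy_session("X", "control", 2, c(rep(TRUE, 6), rep(FALSE, 6)), t0)
  expect_equal(help_ratio(s), 6 / 18, tolerance = 1e-12)
  s$attempts[[1]] <- s$attempts[[1]][0, ]
  expect_error(help_ratio(s), "no tries")
})

test_that("the gain table pairs sessions and derives per-learner fields", {
  g <- gain_table(toy_log())
  expect_equal(nrow(g), 2)
  a <- g[g$learner_id == "A", ]
  expect_equal(a$pre, 50)
  expect_equal(a$post, 100 * 10 / 12, tolerance = 1e-9)
  expect_equal(a$gain, (a$post - 50) / 50, tolerance = 1e-9)
  expect_equal(as.character(a$spacing), "<=1 day")
  b <- g[g$learner_id == "B", ]
  expect_equal(as.character(b$spacing), "<=1 month")
  expect_equal(b$help_ratio, 0)
  expect_equal(b$gain, 1)
})

test_that("perfect pretests are excluded from gains and logged", {
  t0 <- as.POSIXct("2019-03-01", tz = "UTC")
  log <- dplyr::bind_rows(
    toy_log(),
    toy_session("C", "control", 1, rep(TRUE, 12), t0),
    toy_session("C", "control", 2, rep(TRUE, 12), t0 + 7200))
  g <- gain_table(log)
  expect_false("C" %in% g$learner_id)
  excl <- attr(g, "excluded")
  expect_equal(excl$learner_id, "C")
  expect_match(excl$reason, "pretest score 100")
})

test_that("single-group effect sizes reproduce the published arm rows", {
  ctl <- single_group_effect(table2_control())
  trt <- single_group_effect(table2_experiment())
  expect_equal(round(trt$estimate, 3), 1.272)
  expect_lt(abs(ctl$estimate - 1.031), 0.01)
  expect_lt(abs(trt$ci_low - 0.966), 0.02)
  expect_lt(abs(trt$ci_high - 1.577), 0.02)
  expect_lt(abs(ctl$ci_low - 0.789), 0.02)
  expect_lt(abs(ctl$ci_high - 1.274), 0.02)
})

test_that("single-group effect size is scale invariant and null at no change", {
  s <- arm_summary(50, 40, 10, 40, 12, 0.3)
  expect_equal(single_group_effect(s)$estimate, 0)
  a <- arm_summary(80, 45, 12, 70, 15, 0.4)
  b <- arm_summary(80, 450, 120, 700, 150, 0.4)
  expect_equal(single_group_effect(a)$estimate,
               single_group_effect(b)$estimate, tolerance = 1e-12)
  expect_error(single_group_effect(arm_summary(50, 40, 10, 50, 10, 1)),
               "r = 1")
})

test_that("alternative standardizers are available but not the default", {
  s <- table2_experiment()
  d_default <- single_group_effect(s)$estimate
  d_change <- single_group_effect(s, standardizer = "change_sd")$estimate
  d_pooled <- single_group_effect(s,
                                  standardizer = "pooled_prepost")$estimate
  expect_false(isTRUE(all.equal(d_default, d_change)))
  expect_false(isTRUE(all.equal(d_default, d_pooled)))
})

test_that("Morris G from the published arm rows gives the headline effect", {
  g <- morris_g(table2_experiment(), table2_control(), correction = 0.998)
  expect_equal(round(g$estimate, 2), 0.09)
  g_pre <- morris_g(table2_experiment(), table2_control(),
                    correction = 0.998, pooling = "pretest_only")
  expect_equal(round(g_pre$estimate, 2), 0.08)
  expect_equal(g$correction, 0.998)
  expect_true(g$ci_low <= g$estimate && g$estimate <= g$ci_high)
})

test_that("Morris G is null for identical arms and antisymmetric", {
  a <- arm_summary(60, 50, 20, 75, 18, 0.3)
  b <- arm_summary(80, 55, 22, 72, 19, 0.25)
  expect_equal(morris_g(a, a)$estimate, 0)
  expect_equal(morris_g(a, b)$estimate, -morris_g(b, a)$estimate,
               tolerance = 1e-12)
})

test_that("the correction factor can be derived from the pooling df", {
  a <- arm_summary(60, 50, 20, 75, 18, 0.3)
  b <- arm_summary(80, 55, 22, 72, 19, 0.25)
  g <- morris_g(a, b, correction = NULL)
  df <- 2 * (59 + 79)  # all four pre/post cells contribute their df
  expect_equal(g$correction, 1 - 3 / (4 * df - 1))
  expect_gt(g$correction, 0.9)
  expect_lte(g$correction, 1)
})
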