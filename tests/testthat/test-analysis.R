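test_that("the gain regression recovers injected covariate effects", {
  dat <- make_gain_data(250, arm_effect = 0.5,
                        spacing_effects = c(0, -0.1, -0.3),
                        help_effect = -0.8, seed = 42)
  fit <- fit_gain_regression(dat)
  cf <- fit$coefficients
  arm_row <- cf[grepl("^arm", cf$term), ]
  expect_true(arm_row$ci_low <= 0.5 && 0.5 <= arm_row$ci_high)
  sp_row <- cf[grepl("1 month", cf$term), ]
  expect_true(sp_row$ci_low <= -0.3 && -0.3 <= sp_row$ci_high)
  hp_row <- cf[cf$term == "help_ratio", ]
  expect_lt(hp_row$estimate, 0)
  expect_true(fit$adj_r2 > 0 && fit$adj_r2 <= 1)
  expect_true(fit$bp_pvalue > 0 && fit$bp_pvalue <= 1)
  expect_true(all(fit$vif >= 1))
  # CI bounds bracket each estimate
  expect_true(all(cf$ci_low <= cf$estimate & cf$estimate <= cf$ci_high))
})

test_that("injected effect signs are recovered consistently across seeds", {
  hits <- 0L
  for (s in 1:40) {
    dat <- make_gain_data(250, arm_effect = 0.5,
                          spacing_effects = c(0, -0.1, -0.3),
                          help_effect = -0.8, seed = 100 + s)
    cf <- fit_gain_regression(dat)$coefficients
    ok <- cf$estimate[grepl("^arm", cf$term)] > 0 &&
      cf$estimate[grepl("1 month", cf$term)] < 0 &&
      cf$estimate[cf$term == "help_ratio"] < 0
    hits <- hits + ok
  }
  expect_gte(hits / 40, 0.95)
})

test_that("exact collinearity raises a singularity error naming the column", {
  dat <- make_gain_data(100, seed = 3)
  dat$help_twin <- dat$help_ratio
  spec <- regression_spec(predictors = c("arm", "help_ratio", "help_twin"))
  expect_error(fit_gain_regression(dat, spec), "help_twin")
})

test_that("standardized continuous predictors are centered and scaled", {
  dat <- make_gain_data(200, seed = 5)
  fit <- fit_gain_regression(dat)
  x <- fit$model$model$time_on_task
  expect_equal(mean(x), 0, tolerance = 1e-8)
  expect_equal(sd(x), 1, tolerance = 1e-8)
})

test_that("Welch test on published summaries reproduces the age-row p", {
  res <- welch_t_summary(31.2, 8.26, 103, 29.4, 6.99, 72)
  expect_equal(round(res$p_value, 2), 0.12)
  # matches stats::t.test on data with those exact moments
  set.seed(9)
  a <- rnorm(103); a <- (a - mean(a)) / sd(a) * 8.26 + 31.2
  b <- rnorm(72); b <- (b - mean(b)) / sd(b) * 6.99 + 29.4
  tt <- t.test(a, b)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-6)
})

test_that("attrition tests handle equal groups and degenerate variables", {
  df <- tibble::tibble(age = c(30, 31, 32, 33), cadre = c("a", "a", "b", "b"),
                       flat = 1)
  res <- attrition_tests(df, df, continuous = c("age", "flat"),
                         categorical = "cadre")
  expect_equal(res$p_value[res$variable == "age"], 1, tolerance = 1e-9)
  expect_match(res$note[res$variable == "flat"], "zero variance")
  prop_rows <- res[res$type == "two_prop_z", ]
  expect_true(all(prop_rows$p_value == 1))
})

test_that("the Welch attrition test holds its nominal size", {
  set.seed(123)
  reps <- 1000
  rej <- 0L
  for (i in seq_len(reps)) {
    x1 <- rnorm(40)
    x2 <- rnorm(55)
    r <- welch_t_summary(mean(x1), sd(x1), 40, mean(x2), sd(x2), 55)
    rej <- rej + (r$p_value < 0.05)
  }
  expect_lt(abs(rej / reps - 0.05), 0.02)
})

test_that("the variance-homogeneity test is calibrated and detects scale", {
  set.seed(77)
  over <- 0L
  for (i in 1:100) {
    x <- c(rnorm(200), rnorm(200))
    gls <- rep(c("a", "b"), each = 200)
    over <- over + (levene_test(x, gls)$p_value > 0.05)
  }
  expect_gte(over / 100, 0.90)
  # separation: one group at five times the scale
  set.seed(78)
  x <- c(rnorm(200, sd = 1), rnorm(200, sd = 5))
  res <- levene_test(x, rep(c("a", "b"), each = 200))
  expect_lt(res$p_value, 0.001)
  # joint permutation of labels and values leaves W unchanged
  perm <- sample(400)
  res_joint <- levene_test(x[perm], rep(c("a", "b"), each = 200)[perm])
  expect_equal(res_joint$statistic, res$statistic)
  expect_error(levene_test(rnorm(10), rep("a", 10)), "two groups")
})

test_that("the paired design needs 83 per group for d = 0.22", {
  res <- required_sample_size(power_spec(0.22, 0.05, 0.80, "one_sample"))
  expect_identical(res$per_group, 83L)
  res_p <- required_sample_size(power_spec(0.22, 0.05, 0.80, "paired"))
  expect_identical(res_p$per_group, 83L)
  approx <- required_sample_size(power_spec(0.22, 0.05, 0.80, "one_sample"),
                                 method = "normal_approx")
  expect_equal(approx$n_exact, 162.2, tolerance = 0.05)
})

test_that("required sample size is strictly decreasing in the effect size", {
  ns <- vapply(c(0.22, 0.44, 0.88), function(d)
    required_sample_size(power_spec(d, 0.05, 0.80, "one_sample"))$total, 0)
  expect_true(all(diff(ns) < 0))
  spec0 <- power_spec(0.22)
  spec0$effect_size <- 0
  expect_error(required_sample_size(spec0), "positive")
})

test_that("two-sample and one-way ANOVA designs agree on sample size", {
  two <- required_sample_size(power_spec(0.5, 0.05, 0.80, "two_sample"))
  aov <- required_sample_size(power_spec(0.5, 0.05, 0.80, "anova_oneway"))
  expect_lt(abs(two$total - aov$total), 3)
})

test_that("simulated power matches nominal size and grows with n", {
  null_spec <- power_spec(1e-12, 0.05, 0.8, "one_sample")
  null_spec$effect_size <- 0
  res0 <- power_simulation(null_spec, n = 50, reps = 10000, seed = 5)
  expect_lt(abs(res0$power - 0.05), 0.01)
  spec <- power_spec(0.22, 0.05, 0.80, "one_sample")
  pw <- vapply(c(50, 100, 166, 300), function(n)
    power_simulation(spec, n, reps = 4000, seed = 6)$power, 0)
  expect_true(all(diff(pw) > 0))
})

test_that("solved sample sizes achieve the target power in simulation", {
  spec <- power_spec(0.22, 0.05, 0.80, "one_sample")
  res <- required_sample_size(spec)
  sim <- power_simulation(spec, n = res$total, reps = 10000, seed = 13)
  expect_gte(sim$power, spec$power - 1.5 * sim$mc_se)
})
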