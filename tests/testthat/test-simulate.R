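test_that("arm allocation recodes the 0-3 draw as a coin flip", {
  expect_identical(allocate_arm(0), "control")
  expect_identical(allocate_arm(1), "control")
  expect_identical(allocate_arm(2), "experiment")
  expect_identical(allocate_arm(3), "experiment")
  expect_error(allocate_arm(4), "0, 1, 2, 3")
  expect_error(allocate_arm(-1), "0, 1, 2, 3")
})

test_that("symmetric allocation yields a near-even split at n = 10,000", {
  cfg <- trial_config(n_enrolled = 10000L,
                      allocation_prob_experiment = 0.5)
  pop <- generate_population(cfg, seed = 21)
  frac <- mean(pop$arm == "experiment")
  expect_lt(abs(frac - 0.5), 0.015)
})

test_that("biased allocation reproduces the observed completer imbalance", {
  cfg <- trial_config(n_enrolled = 247L,
                      allocation_prob_experiment = 0.40)
  pop <- generate_population(cfg, seed = 8)
  n_exp <- sum(pop$arm == "experiment")
  # 95% binomial band around 98.8
  band <- 1.96 * sqrt(247 * 0.4 * 0.6)
  expect_lt(abs(n_exp - 98.8), band + 1)
})

test_that("population generation is deterministic and marginally calibrated", {
  cfg <- trial_config(n_enrolled = 5000L)
  p1 <- generate_population(cfg, seed = 3)
  p2 <- generate_population(cfg, seed = 3)
  expect_identical(p1, p2)
  expect_equal(mean(p1$cadre == "doctor"), 0.383, tolerance = 0.05)
  expect_equal(mean(p1$cadre == "nurse"), 0.389, tolerance = 0.05)
  expect_equal(mean(p1$level == "student"), 0.331, tolerance = 0.05)
  expect_equal(mean(p1$prior_etat), 0.611, tolerance = 0.05)
  expect_true(all(p1$age > 0) && all(p1$experience >= 0))
  # empty population
  expect_identical(nrow(generate_population(
    trial_config(n_enrolled = 0L))), 0L)
})

test_that("forgetting decays mastery toward the prior in closed form", {
  p <- bkt_params(0.3, 0.2, 0.1, 0.2)
  s <- knowledge_state(0.9, 5L)
  out <- apply_forgetting(s, p, elapsed_days = 30, rate = 0.1)
  expect_equal(out$p_know, 0.3 + 0.6 * exp(-3), tolerance = 1e-6)
  expect_identical(out$opportunities, 5L)
  expect_equal(apply_forgetting(s, p, 0, 0.1)$p_know, 0.9)
  expect_equal(apply_forgetting(s, p, 365, 0)$p_know, 0.9)
  expect_error(apply_forgetting(s, p, -1, 0.1), "non-negative")
  # longer gaps never yield higher mastery
  gaps <- c(0, 0.5, 1, 5, 20, 100)
  know <- vapply(gaps, function(g)
    apply_forgetting(s, p, g, 0.1)$p_know, 0)
  expect_true(all(diff(know) <= 0))
  expect_true(all(know >= p$p_init))
})

test_that("a perfect learner scores 100 with no feedback", {
  cfg <- trial_config(p_slip = 0, n_enrolled = 1L)
  lrn <- generate_population(cfg, seed = 1)[1, ]
  set.seed(2)
  out <- simulate_session(lrn, states = rep(1, cfg$tasks_per_session), cfg)
  expect_equal(out$record$score, 100)
  expect_true(out$record$completed)
  expect_equal(sum(!is.na(out$record$attempts[[1]]$feedback_level)), 0)
})

test_that("a floor learner with no guessing and cap 1 scores zero", {
  cfg <- trial_config(p_guess = 0, attempt_cap = 1L, n_enrolled = 1L)
  lrn <- generate_population(cfg, seed = 1)[1, ]
  set.seed(2)
  out <- simulate_session(lrn, states = rep(0, cfg$tasks_per_session), cfg)
  expect_equal(out$record$score, 0)
  expect_false(out$record$completed)
})

test_that("session scores equal the first-attempt fraction exactly", {
  log <- simulate_trial(small_config())
  for (i in seq_len(min(nrow(log$sessions), 50))) {
    s <- log$sessions[i, ]
    att <- s$attempts[[1]]
    first <- att[att$attempt_index == 1L, ]
    expect_equal(s$score, 100 * mean(first$correct == 1))
    expect_gte(s$score, 0)
    expect_lte(s$score, 100)
  }
})

test_that("identical config and seed reproduce the trial byte-for-byte", {
  log1 <- simulate_trial(small_config())
  log2 <- simulate_trial(small_config())
  expect_identical(log1$sessions, log2$sessions)
  expect_identical(log1$learners, log2$learners)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(log1, p1)
  write_event_log(log2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("retention controls progression to the second session", {
  cfg <- trial_config(n_enrolled = 150L, retention_per_round = 1)
  log <- simulate_trial(cfg, seed = 4)
  expect_true(all(log$learners$n_sessions == 2))
  cfg5 <- trial_config(n_enrolled = 572L, retention_per_round = 0.5)
  log5 <- simulate_trial(cfg5, seed = 4)
  reached <- sum(log5$learners$n_sessions >= 2)
  # 95% binomial band around 286
  expect_lt(abs(reached - 286), 1.96 * sqrt(572 * 0.25) + 1)
})

test_that("first sessions at control defaults hit the pretest calibration", {
  cfg <- trial_config(n_enrolled = 1000L,
                      allocation_prob_experiment = 0)
  log <- simulate_trial(trial_config(n_enrolled = 1000L,
                                     allocation_prob_experiment = 0,
                                     n_rounds = 1L), seed = 31)
  pre <- log$sessions$score[log$sessions$session_index == 1]
  expect_lt(abs(mean(pre) - 56.1), 2)
})

test_that("a stronger feedback-uptake configuration shifts gains to the
           experiment arm end-to-end", {
  # slow intrinsic learning so the feedback boosts carry the effect; the
  # adaptive arm receives its (stronger) messages a failure earlier
  cfg <- trial_config(n_enrolled = 1200L, retention_per_round = 1,
                      ability_mean_control = 0.35,
                      ability_mean_experiment = 0.35,
                      allocation_prob_experiment = 0.5,
                      p_learn = 0.15,
                      feedback_uptake = c(0, 0.7, 0.9))
  g <- gain_table(simulate_trial(cfg, seed = 17))
  ctl <- g[g$arm == "control", ]
  trt <- g[g$arm == "experiment", ]
  expect_gt(mean(trt$gain), mean(ctl$gain))
  res <- morris_g(arm_summarize(trt$pre, trt$post),
                  arm_summarize(ctl$pre, ctl$post))
  expect_gt(res$estimate, 0)
})
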