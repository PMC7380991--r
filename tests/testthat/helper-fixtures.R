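# Published arm summaries of the emulated trial (percent-score scale)
table2_control <- function() arm_summary(148, 56.1, 23.2, 85.8, 15.6, 0.226)
table2_experiment <- function() arm_summary(99, 50.4, 21.4, 81.8, 17.7, 0.335)

# hand-built one-session record: `first` is the vector of first-attempt
# correctness flags; extra incorrect attempts (with feedback) are appended
# for tasks failed on the first try
toy_session <- function(learner_id, arm, session_index, first,
                        start, minutes = 10, feedback_level = 2L) {
  n <- length(first)
  rows <- lapply(seq_len(n), function(k) {
    if (first[k]) {
      tibble::tibble(task_id = sprintf("task_%02d", k), attempt_index = 1L,
                     correct = 1L, feedback_level = NA_integer_,
                     p_next = NA_real_)
    } else {
      tibble::tibble(task_id = sprintf("task_%02d", k),
                     attempt_index = c(1L, 2L), correct = c(0L, 1L),
                     feedback_level = c(feedback_level, NA_integer_),
                     p_next = c(0.5, NA_real_))
    }
  })
  tibble::tibble(
    learner_id = learner_id, arm = arm,
    session_index = as.integer(session_index),
    start = start, end = start + minutes * 60,
    score = 100 * mean(first), completed = TRUE,
    attempts = list(dplyr::bind_rows(rows))
  )
}

# two-session toy log for two learners with known scores and spacing
toy_log <- function() {
  t0 <- as.POSIXct("2019-03-01 08:00:00", tz = "UTC")
  dplyr::bind_rows(
    toy_session("A", "control", 1, c(rep(TRUE, 6), rep(FALSE, 6)), t0),
    toy_session("A", "control", 2, c(rep(TRUE, 10), rep(FALSE, 2)),
                t0 + 3 * 3600),
    toy_session("B", "experiment", 1, c(rep(TRUE, 3), rep(FALSE, 9)), t0,
                feedback_level = 1L),
    toy_session("B", "experiment", 2, rep(TRUE, 12), t0 + 10 * 86400,
                feedback_level = 1L)
  )
}

# synthetic gain records with injected covariate effects, used by the
# regression recovery and coverage tests
make_gain_data <- function(n, arm_effect = 0, spacing_effects = c(0, 0, 0),
                           help_effect = 0, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  spacing <- factor(sample(unname(SPACING_LABELS), n, replace = TRUE),
                    levels = unname(SPACING_LABELS))
  arm <- sample(c("control", "experiment"), n, replace = TRUE,
                prob = c(0.6, 0.4))
  time_on_task <- rlnorm(n, log(25), 0.4)
  help_ratio <- rbeta(n, 2, 6)
  prior_etat <- runif(n) < 0.6
  eta <- 0.6 + c(0, spacing_effects)[as.integer(spacing)] +
    arm_effect * (arm == "experiment") +
    help_effect * help_ratio
  gain <- eta + rnorm(n, 0, noise_sd)
  tibble::tibble(gain = gain, spacing = spacing, arm = arm,
                 time_on_task = time_on_task, help_ratio = help_ratio,
                 prior_etat = prior_etat)
}

# small, fast simulator configuration for structural tests
small_config <- function(..., seed = 11L) {
  trial_config(n_enrolled = 120L, seed = seed, ...)
}
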