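SPACING_LEVELS <- c("le_1h", "le_1d", "le_1wk", "le_1mo")
SPACING_LABELS <- c(le_1h = "<=1 hour", le_1d = "<=1 day",
                    le_1wk = "<=1 week", le_1mo = "<=1 month")

#' Trial simulator configuration
#'
#' All constants of the generative trial simulator: enrollment size, the
#' coin-flip arm allocation probability, per-arm ability (prior mastery)
#' distributions, BKT learning/slip/guess parameters, the feedback policy
#' thresholds, feedback uptake (extra mastery gained from reading a shown
#' message), the spacing mixture over repeat-session gaps, the between-
#' session forgetting rate, and per-round retention.
#'
#' Defaults encode the study conditions being emulated: 572 enrolled
#' learners, a completer split near 148:99 (allocation probability 0.40 for
#' the experiment arm), 43.2% reaching the second session, pretest means
#' near 56 (control) and 50 (experiment) with SDs near 22, and posttest
#' means in the low-to-mid 80s. Ability is Beta-distributed per arm;
#' spacing is a categorical mixture over four bins (within-bin times
#' uniform); forgetting decays mastery toward the learner's prior at rate
#' `forgetting_rate` per day.
#'
#' @param n_enrolled Number of enrolled learners.
#' @param tasks_per_session Learning tasks per scenario play-through.
#' @param attempt_cap Maximum attempts per task before the task is marked
#'   unfinished.
#' @param allocation_prob_experiment Probability a learner is allocated to
#'   the experiment arm.
#' @param retention_per_round Probability of returning for each subsequent
#'   round.
#' @param n_rounds Maximum number of rounds simulated per learner.
#' @param forgetting_rate Per-day exponential decay of mastery toward the
#'   learner's prior between sessions.
#' @param spacing_probs Mixture probabilities over the four spacing bins
#'   (`<=1h`, `<=1d`, `<=1wk`, `<=1mo`); must sum to 1.
#' @param p_learn,p_slip,p_guess Shared BKT dynamics parameters.
#' @param ability_mean_control,ability_mean_experiment,ability_sd Mean and
#'   SD of the per-learner Beta-distributed prior mastery, by arm.
#' @param feedback_uptake Length-3 vector: extra mastery probability gained
#'   after a level-0/1/2 message is shown.
#' @param tau_low,tau_high Adaptive-policy thresholds (see
#'   [feedback_policy()]).
#' @param dropout_covariate_effect If TRUE, clinical officers and learners
#'   with specialized training get lower retention (logit shift -0.6),
#'   emulating covariate-dependent attrition.
#' @param seed Default seed used by [simulate_trial()].
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_enrolled = 572L,
                         tasks_per_session = 12L,
                         attempt_cap = 5L,
                         allocation_prob_experiment = 0.40,
                         retention_per_round = 0.432,
                         n_rounds = 2L,
                         forgetting_rate = 0.09,
                         spacing_probs = c(le_1h = 0.33, le_1d = 0.27,
                                           le_1wk = 0.22, le_1mo = 0.18),
                         p_learn = 0.60, p_slip = 0.02, p_guess = 0.20,
                         ability_mean_control = 0.472,
                         ability_mean_experiment = 0.385,
                         ability_sd = 0.25,
                         feedback_uptake = c(0, 0.25, 0.40),
                         tau_low = 0.70, tau_high = 0.85,
                         dropout_covariate_effect = FALSE,
                         seed = 2019L) {
  assert_probability(allocation_prob_experiment)
  assert_probability(retention_per_round)
  assert_probability(spacing_probs, allow_vector = TRUE)
  if (abs(sum(spacing_probs) - 1) > 1e-8) {
    stop("`spacing_probs` must sum to 1", call. = FALSE)
  }
  if (length(spacing_probs) != 4) {
    stop("`spacing_probs` must have four bins", call. = FALSE)
  }
  if (tasks_per_session < 1) stop("`tasks_per_session` must be >= 1")
  if (forgetting_rate < 0) stop("`forgetting_rate` must be >= 0")
  if (length(feedback_uptake) != 3 ||
      any(feedback_uptake < 0 | feedback_uptake > 1)) {
    stop("`feedback_uptake` must be 3 probabilities", call. = FALSE)
  }
  structure(list(
    n_enrolled = as.integer(n_enrolled),
    tasks_per_session = as.integer(tasks_per_session),
    attempt_cap = as.integer(attempt_cap),
    allocation_prob_experiment = allocation_prob_experiment,
    retention_per_round = retention_per_round,
    n_rounds = as.integer(n_rounds),
    forgetting_rate = forgetting_rate,
    spacing_probs = stats::setNames(as.numeric(spacing_probs),
                                    SPACING_LEVELS),
    p_learn = p_learn, p_slip = p_slip, p_guess = p_guess,
    ability_mean_control = ability_mean_control,
    ability_mean_experiment = ability_mean_experiment,
    ability_sd = ability_sd,
    feedback_uptake = as.numeric(feedback_uptake),
    tau_low = tau_low, tau_high = tau_high,
    dropout_covariate_effect = isTRUE(dropout_covariate_effect),
    seed = as.integer(seed)
  ), class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>", x$n_enrolled, "learners,",
      x$tasks_per_session, "tasks/session,",
      x$n_rounds, "rounds, retention", x$retention_per_round, "\n")
  invisible(x)
}

#' Map an in-app random draw to a study arm
#'
#' The deployed randomization drew an integer between 0 and 3 on first app
#' launch; draws of 0 or 1 were recoded to the control arm and draws of 2
#' or 3 to the experiment arm, mimicking a coin toss.
#'
#' @param rng_draw Integer draw(s) in `{0, 1, 2, 3}`.
#' @return Character vector, `"control"` or `"experiment"`.
#' @examples
#' allocate_arm(c(0, 1, 2, 3))
#' @export
allocate_arm <- function(rng_draw) {
  if (anyNA(rng_draw) || !all(rng_draw %in% 0:3)) {
    stop("`rng_draw` must be in {0, 1, 2, 3}", call. = FALSE)
  }
  ifelse(rng_draw <= 1, "control", "experiment")
}

# Beta shape parameters from mean/sd, guarding impossible variances
beta_shapes <- function(mean, sd) {
  v <- min(sd^2, mean * (1 - mean) * 0.98)
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

# Baseline covariate frequencies of the study population (learners who
# provided background information)
COVARIATE_FREQS <- list(
  cadre = c(doctor = 0.383, clinical_officer = 0.154,
            nurse = 0.389, other = 0.074),
  level = c(student = 0.331, intern = 0.091,
            general_officer = 0.383, specialized = 0.194),
  prior_etat = 0.611,
  age_mean = 30.5, age_sd = 7.8,
  experience_mean = 6.9, experience_sd = 7.4
)

#' Generate a synthetic learner population
#'
#' Draws learner covariates (cadre, training level, age, experience, prior
#' exposure to the emergency-care curriculum) from the baseline frequencies
#' of the emulated study, allocates arms via the coin-flip scheme with a
#' configurable bias (`allocation_prob_experiment`) to emulate the observed
#' arm imbalance, and draws each learner's prior mastery (ability) from the
#' arm's Beta distribution.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A tibble with one row per learner: `learner_id`, `arm`, `cadre`,
#'   `level`, `age`, `experience`, `prior_etat`, `ability`, `enrol_day`.
#' @export
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(as.integer(seed))
  n <- config$n_enrolled
  if (n == 0) {
    return(tibble::tibble(learner_id = character(), arm = character(),
                          cadre = character(), level = character(),
                          age = numeric(), experience = numeric(),
                          prior_etat = logical(), ability = numeric(),
                          enrol_day = numeric()))
  }
  p <- config$allocation_prob_experiment
  draws <- sample(0:3, n, replace = TRUE,
                  prob = c((1 - p) / 2, (1 - p) / 2, p / 2, p / 2))
  arm <- allocate_arm(draws)
  fr <- COVARIATE_FREQS
  age <- pmin(pmax(rnorm(n, fr$age_mean, fr$age_sd), 19), 70)
  shp <- (fr$experience_mean / fr$experience_sd)^2
  experience <- pmin(stats::rgamma(n, shape = shp,
                                   scale = fr$experience_mean / shp), 40)
  ab <- numeric(n)
  for (a in c("control", "experiment")) {
    m <- if (a == "control") config$ability_mean_control
         else config$ability_mean_experiment
    sh <- beta_shapes(m, config$ability_sd)
    idx <- which(arm == a)
    ab[idx] <- rbeta(length(idx), sh[1], sh[2])
  }
  tibble::tibble(
    learner_id = sprintf("HCP%04d", seq_len(n)),
    arm = arm,
    cadre = sample(names(fr$cadre), n, replace = TRUE, prob = fr$cadre),
    level = sample(names(fr$level), n, replace = TRUE, prob = fr$level),
    age = round(age, 1),
    experience = round(experience, 1),
    prior_etat = runif(n) < fr$prior_etat,
    ability = ab,
    enrol_day = round(runif(n, 0, 180), 3)
  )
}

#' Apply between-session forgetting to a knowledge state
#'
#' Between sessions, mastery decays exponentially toward the learner's
#' prior: `L' = p_init + (L - p_init) * exp(-rate * elapsed)`. Mastery never
#' drops below the prior, elapsed time of zero (or a zero rate) leaves the
#' state unchanged, and longer gaps never yield higher mastery. Forgetting
#' is deliberately kept outside the within-session BKT updates, which
#' assume no forgetting.
#'
#' @param state A [knowledge_state()].
#' @param params The learner's [bkt_params()] (supplies the prior floor).
#' @param elapsed_days Non-negative elapsed time in days.
#' @param rate Per-day decay rate (>= 0).
#' @return The decayed [knowledge_state()] (opportunity count unchanged).
#' @examples
#' apply_forgetting(knowledge_state(0.9), bkt_params(0.3, 0.2, 0.1, 0.2),
#'                  elapsed_days = 30, rate = 0.1)
#' @export
apply_forgetting <- function(state, params, elapsed_days, rate) {
  stopifnot(inherits(state, "knowledge_state"),
            inherits(params, "bkt_params"))
  if (!is.numeric(elapsed_days) || length(elapsed_days) != 1L ||
      is.na(elapsed_days) || elapsed_days < 0) {
    stop("`elapsed_days` must be a single non-negative number",
         call. = FALSE)
  }
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  L <- params$p_init +
    (state$p_know - params$p_init) * exp(-rate * elapsed_days)
  knowledge_state(L, state$opportunities)
}

forget_vec <- function(L, floor, elapsed_days, rate) {
  floor + (L - floor) * exp(-rate * elapsed_days)
}

#' Simulate one learning session
#'
#' Plays one scenario round for a learner: for each task, attempts are
#' drawn Bernoulli with the BKT-predicted success probability until the
#' task is answered correctly or the attempt cap is hit. Every incorrect
#' attempt triggers a feedback message chosen by the arm's policy (with the
#' predicted next-attempt probability computed after the posterior update
#' for the observed failure), and reading a message can itself raise
#' mastery (`feedback_uptake`). The first-attempt correctness flags yield
#' the session score.
#'
#' Randomness is drawn from R's global RNG stream; seed the caller.
#'
#' @param learner One-row learner tibble (see [generate_population()]).
#' @param states Numeric vector of per-task mastery probabilities.
#' @param config A [trial_config()].
#' @param session_index 1-based session number.
#' @param start Session start time (POSIXct, UTC).
#' @return A list with `record` (one-row session tibble with nested
#'   `attempts`) and `states` (updated mastery vector).
#' @export
simulate_session <- function(learner, states, config, session_index = 1L,
                             start = as.POSIXct("2019-02-01", tz = "UTC")) {
  stopifnot(inherits(config, "trial_config"))
  n_tasks <- config$tasks_per_session
  stopifnot(length(states) == n_tasks)
  S <- config$p_slip; G <- config$p_guess; T_ <- config$p_learn
  policy <- feedback_policy(config$tau_low, config$tau_high,
                            arm = "experiment")
  arm <- learner$arm
  uptake <- config$feedback_uptake
  task_id <- integer(0); attempt_index <- integer(0)
  correct <- integer(0); feedback_level <- integer(0); p_next <- numeric(0)
  first_correct <- logical(n_tasks)
  complete <- TRUE
  for (k in seq_len(n_tasks)) {
    L <- states[k]
    solved <- FALSE
    for (i in seq_len(config$attempt_cap)) {
      pc <- L * (1 - S) + (1 - L) * G
      ok <- runif(1) < pc
      L <- bkt_update_vec(L, as.integer(ok), S, G, T_)
      task_id <- c(task_id, k); attempt_index <- c(attempt_index, i)
      correct <- c(correct, as.integer(ok))
      if (ok) {
        feedback_level <- c(feedback_level, NA_integer_)
        p_next <- c(p_next, NA_real_)
        if (i == 1L) first_correct[k] <- TRUE
        solved <- TRUE
        break
      }
      pn <- L * (1 - S) + (1 - L) * G
      lev <- select_feedback_level(arm, i, pn, policy)
      feedback_level <- c(feedback_level, lev)
      p_next <- c(p_next, pn)
      L <- L + (1 - L) * uptake[lev + 1L]
    }
    if (!solved) complete <- FALSE
    states[k] <- L
  }
  n_att <- length(task_id)
  duration <- sum(rlnorm(n_att, log(40), 0.5))
  attempts <- tibble::tibble(
    task_id = sprintf("task_%02d", task_id),
    attempt_index = attempt_index,
    correct = correct,
    feedback_level = feedback_level,
    p_next = round(p_next, 6)
  )
  score <- 100 * mean(first_correct)
  record <- tibble::tibble(
    learner_id = learner$learner_id,
    arm = arm,
    session_index = as.integer(session_index),
    start = start,
    end = start + duration,
    score = score,
    completed = complete,
    attempts = list(attempts)
  )
  list(record = record, states = states)
}

draw_spacing_days <- function(probs) {
  bin <- sample(SPACING_LEVELS, 1, prob = probs)
  switch(bin,
         le_1h = runif(1, 5 / 1440, 1 / 24),
         le_1d = runif(1, 1 / 24, 1),
         le_1wk = runif(1, 1, 7),
         le_1mo = runif(1, 7, 31))
}

#' Simulate a full two-arm trial
#'
#' Generates a learner population, then for each learner plays the first
#' session, draws per-round survival (retention), a spacing gap from the
#' configured mixture, applies forgetting to the per-task mastery states,
#' and plays subsequent sessions, up to `n_rounds`. The result is a
#' seed-reproducible event log.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An object of class `trial_log`: a list with `learners` (the
#'   population table, plus `n_sessions` and `completer` flags), `sessions`
#'   (one row per session with nested attempts) and `config`.
#' @export
simulate_trial <- function(config = trial_config(), seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  learners <- generate_population(config, seed = seed)
  origin <- as.POSIXct("2019-02-01 00:00:00", tz = "UTC")
  out <- vector("list", nrow(learners) * config$n_rounds)
  slot <- 0L
  n_sessions <- integer(nrow(learners))
  for (i in seq_len(nrow(learners))) {
    lrn <- learners[i, ]
    states <- rep(lrn$ability, config$tasks_per_session)
    start <- origin + lrn$enrol_day * 86400 + round(runif(1, 0, 43200))
    for (r in seq_len(config$n_rounds)) {
      sess <- simulate_session(lrn, states, config, session_index = r,
                               start = start)
      slot <- slot + 1L
      out[[slot]] <- sess$record
      states <- sess$states
      n_sessions[i] <- r
      if (r == config$n_rounds) break
      retention <- config$retention_per_round
      if (config$dropout_covariate_effect &&
          (lrn$cadre == "clinical_officer" || lrn$level == "specialized")) {
        retention <- stats::plogis(stats::qlogis(retention) - 0.6)
      }
      if (runif(1) >= retention) break
      gap <- draw_spacing_days(config$spacing_probs)
      states <- forget_vec(states, lrn$ability, gap,
                           config$forgetting_rate)
      start <- sess$record$end + gap * 86400
    }
  }
  sessions <- dplyr::bind_rows(out[seq_len(slot)])
  done <- sessions[sessions$completed, , drop = FALSE]
  ncomp <- table(done$learner_id)
  learners$n_sessions <- n_sessions
  learners$completer <- learners$learner_id %in%
    names(ncomp)[ncomp >= 2]
  structure(list(learners = learners, sessions = sessions,
                 config = config),
            class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  cat("<trial_log>", nrow(x$learners), "learners,",
      nrow(x$sessions), "sessions,",
      sum(x$learners$completer), "completers\n")
  invisible(x)
}
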