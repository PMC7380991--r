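#' Feedback policy configuration
#'
#' The adaptive arm chooses among three cascading feedback detail levels
#' based on the predicted probability that the learner's next attempt will
#' be correct: level 0 (minimal retry prompt) when the prediction is at or
#' above `tau_high`, level 1 (reflective) between the thresholds, and level
#' 2 (detailed explanation) below `tau_low`. The deployed cutoffs were never
#' published, so the defaults (0.4, 0.7) are a documented package choice and
#' both thresholds are configurable.
#'
#' @param tau_low Lower threshold, in (0, 1).
#' @param tau_high Upper threshold, in (`tau_low`, 1).
#' @param arm Which arm this policy belongs to, `"control"` or
#'   `"experiment"`.
#' @return An object of class `feedback_policy`.
#' @export
feedback_policy <- function(tau_low = 0.4, tau_high = 0.7,
                            arm = c("experiment", "control")) {
  arm <- match.arg(arm)
  assert_probability(tau_low)
  assert_probability(tau_high)
  if (!(tau_low > 0 && tau_low < tau_high && tau_high < 1)) {
    stop("need 0 < tau_low < tau_high < 1", call. = FALSE)
  }
  structure(list(tau_low = tau_low, tau_high = tau_high, arm = arm),
            class = "feedback_policy")
}

FEEDBACK_LEVELS <- c(minimal = 0L, reflective = 1L, detailed = 2L)

#' Select the feedback level for an incorrect attempt
#'
#' Control-arm learners always get the standardized cascade: a retry prompt
#' (level 0) on the first incorrect attempt and the detailed explanation
#' (level 2) from the second incorrect attempt onward. Experiment-arm
#' learners get the level implied by the predicted next-attempt success
#' probability and the policy thresholds; the mapping is monotone
#' non-increasing in `p_next`.
#'
#' @param arm `"control"` or `"experiment"`.
#' @param attempt_index 1-based index of the (incorrect) attempt.
#' @param p_next Predicted probability the next attempt is correct.
#' @param policy A [feedback_policy()].
#' @return Integer feedback level in `{0, 1, 2}`.
#' @export
select_feedback_level <- function(arm, attempt_index, p_next, policy) {
  arm <- match.arg(arm, c("control", "experiment"))
  stopifnot(inherits(policy, "feedback_policy"))
  if (length(attempt_index) != 1L || attempt_index < 1) {
    stop("`attempt_index` must be a single count >= 1", call. = FALSE)
  }
  assert_probability(p_next)
  if (arm == "control") {
    if (attempt_index == 1) 0L else 2L
  } else {
    if (p_next >= policy$tau_high) 0L
    else if (p_next >= policy$tau_low) 1L
    else 2L
  }
}

#' Default feedback message templates
#'
#' Placeholder wording for the three feedback levels; the clinical prose of
#' the deployed training content is out of scope. Templates may reference
#' `{count}` (number of incorrect choices), `{stage}` (scenario stage
#' identifier) and, for level 2, `{incorrect}` (the incorrect choice ids)
#' and `{explanation}` (per-stage explanation of the correct choices, looked
#' up in `stages`).
#'
#' @return A list with elements `level0`, `level1`, `level2` and `stages`.
#' @export
default_feedback_templates <- function() {
  list(
    level0 = "That is not quite right. Please try again.",
    level1 = paste0("{count} of the selected actions are not appropriate ",
                    "at this stage ({stage}). Consider where in the care ",
                    "pathway each action belongs, then try again."),
    level2 = paste0("{count} choices were incorrect at stage {stage}: ",
                    "{incorrect}. {explanation}"),
    stages = list(
      .default = "Review the actions that are appropriate at this stage."
    )
  )
}

#' Compose a feedback message
#'
#' Deterministically renders the message text for a feedback level from the
#' incorrect choices and the scenario stage. Level 0 carries no choice
#' information; level 1 references the count and stage without revealing
#' answers; level 2 enumerates the incorrect choices and appends the
#' stage's explanation of the correct ones.
#'
#' @param level Feedback level in `{0, 1, 2}`.
#' @param incorrect_choice_ids Character vector of incorrect choice ids
#'   (required, non-empty, for levels 1 and 2).
#' @param stage_id Scenario stage identifier.
#' @param templates Template table, see [default_feedback_templates()].
#' @return An object of class `feedback_message` with fields `level`,
#'   `incorrect_count`, `incorrect_choice_ids`, `text`.
#' @export
compose_feedback <- function(level, incorrect_choice_ids = character(),
                             stage_id = "stage_1",
                             templates = default_feedback_templates()) {
  if (!level %in% 0:2) stop("`level` must be 0, 1 or 2", call. = FALSE)
  key <- paste0("level", level)
  if (is.null(templates[[key]])) {
    stop(sprintf("configuration error: no template for key '%s'", key),
         call. = FALSE)
  }
  incorrect_choice_ids <- unique(as.character(incorrect_choice_ids))
  if (level > 0 && length(incorrect_choice_ids) == 0) {
    stop("levels 1-2 require a non-empty set of incorrect choices",
         call. = FALSE)
  }
  text <- templates[[key]]
  n <- length(incorrect_choice_ids)
  text <- gsub("{count}", as.character(n), text, fixed = TRUE)
  text <- gsub("{stage}", as.character(stage_id), text, fixed = TRUE)
  if (level == 2L) {
    expl <- templates$stages[[as.character(stage_id)]] %||%
      templates$stages[[".default"]]
    if (is.null(expl)) {
      stop("configuration error: no stage explanation available",
           call. = FALSE)
    }
    text <- gsub("{incorrect}", paste(sort(incorrect_choice_ids),
                                      collapse = ", "), text, fixed = TRUE)
    text <- gsub("{explanation}", expl, text, fixed = TRUE)
  }
  structure(
    list(level = as.integer(level), incorrect_count = n,
         incorrect_choice_ids = incorrect_choice_ids, text = text),
    class = "feedback_message"
  )
}

#' @export
print.feedback_message <- function(x, ...) {
  cat(sprintf("<feedback level %d> %s\n", x$level, x$text))
  invisible(x)
}

# flatten all attempt rows of a session log (adds learner/arm/session cols)
flatten_attempts <- function(sessions) {
  stopifnot(is.data.frame(sessions), "attempts" %in% names(sessions))
  parts <- lapply(seq_len(nrow(sessions)), function(i) {
    a <- sessions$attempts[[i]]
    if (is.null(a) || nrow(a) == 0) return(NULL)
    a$learner_id <- sessions$learner_id[i]
    a$arm <- sessions$arm[i]
    a$session_index <- sessions$session_index[i]
    a
  })
  dplyr::bind_rows(parts)
}

#' Tally feedback messages by arm and level
#'
#' Counts the feedback messages recorded in a session log, cross-classified
#' by study arm and feedback level (minimal / reflective / detailed), with
#' percentages of the grand total. One message is recorded per incorrect
#' attempt, so the counts partition the incorrect attempts in scope.
#'
#' @param log A trial log (see [simulate_trial()]) or a sessions tibble.
#' @param scope `"all"` counts every message; `"first_two_sessions"`
#'   restricts to the first two sessions of learners who completed at least
#'   two sessions (the trial's primary-endpoint population).
#' @return A tibble with columns `arm`, `minimal`, `reflective`,
#'   `detailed`, `all` plus matching `*_pct` columns; the final row holds
#'   column totals.
#' @export
tally_messages <- function(log, scope = c("all", "first_two_sessions")) {
  scope <- match.arg(scope)
  sessions <- if (is.data.frame(log)) log else log$sessions
  if (scope == "first_two_sessions" && nrow(sessions)) {
    done <- sessions[sessions$completed, , drop = FALSE]
    completers <- names(which(table(done$learner_id) >= 2))
    sessions <- sessions[sessions$learner_id %in% completers &
                           sessions$session_index <= 2, , drop = FALSE]
  }
  att <- flatten_attempts(sessions)
  counts <- matrix(0L, 2, 3,
                   dimnames = list(c("control", "experiment"),
                                   names(FEEDBACK_LEVELS)))
  if (!is.null(att) && nrow(att)) {
    fb <- att[!is.na(att$feedback_level), , drop = FALSE]
    if (nrow(fb)) {
      tab <- table(factor(fb$arm, levels = rownames(counts)),
                   factor(fb$feedback_level, levels = 0:2))
      counts[] <- as.integer(tab)
    }
  }
  total <- sum(counts)
  out <- tibble::tibble(
    arm = c(rownames(counts), "all"),
    minimal = unname(c(counts[, 1], sum(counts[, 1]))),
    reflective = unname(c(counts[, 2], sum(counts[, 2]))),
    detailed = unname(c(counts[, 3], sum(counts[, 3])))
  )
  out$all <- out$minimal + out$reflective + out$detailed
  for (col in c("minimal", "reflective", "detailed", "all")) {
    out[[paste0(col, "_pct")]] <-
      if (total > 0) round(100 * out[[col]] / total, 2) else 0
  }
  out
}

#' Export a message tally as CSV
#'
#' @param tally Output of [tally_messages()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_message_tally <- function(tally, path) {
  write.csv(tally, path, row.names = FALSE)
  invisible(path)
}
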