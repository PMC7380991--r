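#' Score a learning session
#'
#' The session performance score is the percentage of learning tasks whose
#' first attempt was correct: `100 * first-attempt-correct / task count`.
#' Incomplete sessions (a task hit the attempt cap) carry no score and are
#' excluded from gain analyses.
#'
#' @param session A one-row session record (from [simulate_session()] or a
#'   parsed event log).
#' @return Percent score in `[0, 100]`.
#' @export
score_session <- function(session) {
  stopifnot(is.data.frame(session), nrow(session) == 1)
  if (!isTRUE(session$completed)) {
    stop("incomplete session has no score", call. = FALSE)
  }
  att <- session$attempts[[1]]
  first <- att[att$attempt_index == 1L, , drop = FALSE]
  100 * mean(first$correct == 1)
}

#' Normalized learning gain
#'
#' The fraction of achievable improvement realized between two sessions:
#' `(post - pre) / (100 - pre)`. Gains can be negative (performance drops
#' are kept as computed) and equal 1 exactly when the posttest is perfect
#' and the pretest was not. A perfect pretest leaves no headroom, so the
#' gain is undefined: such records return `NA` and should be excluded (and
#' logged) by callers.
#'
#' @param pre,post Percent scores in `[0, 100]` (vectorized).
#' @return Normalized gain(s); `NA` where `pre == 100`.
#' @examples
#' normalized_gain(50, 85)
#' @export
normalized_gain <- function(pre, post) {
  if (any(pre < 0 | pre > 100 | post < 0 | post > 100, na.rm = TRUE)) {
    stop("scores must be percentages in [0, 100]", call. = FALSE)
  }
  ifelse(pre == 100, NA_real_, (post - pre) / (100 - pre))
}

#' Spacing category of a repeat session
#'
#' Bins the gap between the end of the first session and the start of the
#' second into half-open intervals: `(0, 1h]`, `(1h, 24h]`, `(24h, 7d]`,
#' `(7d, 31d]`. Gaps above 31 days are clamped into the last bin and
#' flagged via the `"clamped"` attribute.
#'
#' @param session1_end,session2_start POSIXct timestamps (vectorized), or
#'   numeric gaps in days via `gap_days`.
#' @param gap_days Optional numeric gap in days, overriding the timestamps.
#' @return Factor with levels `<=1 hour`, `<=1 day`, `<=1 week`,
#'   `<=1 month`.
#' @export
spacing_category <- function(session1_end = NULL, session2_start = NULL,
                             gap_days = NULL) {
  if (is.null(gap_days)) {
    gap_days <- as.numeric(difftime(session2_start, session1_end,
                                    units = "days"))
  }
  if (any(gap_days < 0, na.rm = TRUE)) {
    stop("negative interval between sessions", call. = FALSE)
  }
  clamped <- gap_days > 31
  hours <- gap_days * 24
  idx <- ifelse(hours <= 1, 1L,
         ifelse(hours <= 24, 2L,
         ifelse(gap_days <= 7, 3L, 4L)))
  out <- factor(SPACING_LABELS[idx], levels = unname(SPACING_LABELS))
  attr(out, "clamped") <- clamped
  out
}

#' Help ratio of a session
#'
#' The number of feedback messages (hints) shown in a session divided by
#' the total number of attempts (tries) in that session — a proxy for how
#' much scaffolding the learner needed. An all-first-attempt-correct
#' session has ratio 0.
#'
#' @param session A one-row session record with nested attempts.
#' @return Non-negative ratio.
#' @export
help_ratio <- function(session) {
  stopifnot(is.data.frame(session), nrow(session) == 1)
  att <- session$attempts[[1]]
  if (is.null(att) || nrow(att) == 0) {
    stop("session has no tries; help ratio undefined", call. = FALSE)
  }
  sum(!is.na(att$feedback_level)) / nrow(att)
}

#' Build the gain table from a trial log
#'
#' For every learner whose first two sessions are complete, pairs the first
#' session score (pretest) with the second (posttest) and derives the
#' normalized gain, the spacing category of the repeat session, the help
#' ratio of the second session, and total time on task (minutes across both
#' sessions). Learners with a perfect pretest have an undefined gain and
#' are excluded; the exclusions are reported in the `"excluded"` attribute
#' as a QC table.
#'
#' @param log A `trial_log` or a sessions tibble plus `learners` table.
#' @param learners Learner covariate table (when `log` is a tibble).
#' @return A tibble with one row per analyzable completer: `learner_id`,
#'   `arm`, `pre`, `post`, `gain`, `spacing`, `help_ratio`,
#'   `time_on_task`, plus learner covariates.
#' @export
gain_table <- function(log, learners = NULL) {
  sessions <- if (is.data.frame(log)) log else log$sessions
  learners <- learners %||% (if (!is.data.frame(log)) log$learners)
  s12 <- sessions[sessions$session_index <= 2 & sessions$completed, ,
                  drop = FALSE]
  counts <- table(s12$learner_id)
  ids <- names(counts)[counts == 2]
  rows <- lapply(ids, function(id) {
    s <- s12[s12$learner_id == id, , drop = FALSE]
    s <- s[order(s$session_index), , drop = FALSE]
    tibble::tibble(
      learner_id = id,
      arm = s$arm[1],
      pre = s$score[1],
      post = s$score[2],
      spacing = spacing_category(s$end[1], s$start[2])[1],
      help_ratio = help_ratio(s[2, ]),
      time_on_task = as.numeric(difftime(s$end[1], s$start[1], units = "mins")) +
        as.numeric(difftime(s$end[2], s$start[2], units = "mins"))
    )
  })
  out <- dplyr::bind_rows(rows)
  excluded <- tibble::tibble(learner_id = character(), reason = character())
  if (nrow(out)) {
    out$gain <- normalized_gain(out$pre, out$post)
    perfect <- is.na(out$gain)
    if (any(perfect)) {
      excluded <- tibble::tibble(
        learner_id = out$learner_id[perfect],
        reason = "pretest score 100: normalized gain undefined")
    }
    out <- out[!perfect, , drop = FALSE]
    out$spacing <- factor(as.character(out$spacing),
                          levels = unname(SPACING_LABELS))
    if (!is.null(learners)) {
      out <- dplyr::left_join(
        out,
        learners[, intersect(c("learner_id", "cadre", "level", "age",
                               "experience", "prior_etat"),
                             names(learners))],
        by = "learner_id")
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Arm summary statistics
#'
#' The sufficient statistics of one arm for pre/post effect-size work:
#' sample size, pretest and posttest means and SDs (percent scale), and
#' the Pearson correlation between a learner's pretest and posttest
#' scores.
#'
#' @param n Number of paired observations (>= 2).
#' @param pre_mean,pre_sd,post_mean,post_sd Percent-score moments.
#' @param r Pre/post Pearson correlation.
#' @return An object of class `arm_summary`.
#' @export
arm_summary <- function(n, pre_mean, pre_sd, post_mean, post_sd, r) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (pre_sd <= 0 || post_sd <= 0) stop("SDs must be positive",
                                        call. = FALSE)
  if (abs(r) > 1) stop("`r` must lie in [-1, 1]", call. = FALSE)
  structure(list(n = as.integer(n), pre_mean = pre_mean, pre_sd = pre_sd,
                 post_mean = post_mean, post_sd = post_sd, r = r),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("<arm_summary> n=%d  pre %.1f (%.1f)  post %.1f (%.1f)  r=%.3f\n",
              x$n, x$pre_mean, x$pre_sd, x$post_mean, x$post_sd, x$r))
  invisible(x)
}

#' Summarize an arm from paired scores
#'
#' @param pre,post Paired percent scores.
#' @return An [arm_summary()].
#' @export
arm_summarize <- function(pre, post) {
  keep <- complete.cases(pre, post)
  pre <- pre[keep]; post <- post[keep]
  arm_summary(length(pre), mean(pre), sd(pre), mean(post), sd(post),
              cor(pre, post))
}

effect_size_result <- function(estimate, ci_low, ci_high, correction,
                               method, conf_level = 0.95) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 correction = correction, method = method,
                 conf_level = conf_level),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("<effect_size (%s)> %.3f  %d%% CI [%.3f, %.3f]",
              x$method, x$estimate, round(100 * x$conf_level),
              x$ci_low, x$ci_high))
  if (!is.null(x$correction) && x$correction != 1) {
    cat(sprintf("  (correction %.3f)", x$correction))
  }
  cat("\n")
  invisible(x)
}

#' Single-group pretest-posttest effect size
#'
#' Standardized intra-individual change for one arm. The default
#' standardizer divides the mean change by `pre_sd * sqrt(2 * (1 - r))`,
#' i.e. the SD of change scores implied by the pretest SD under equal
#' pre/post variances, which accounts for the pre/post correlation.
#' Alternative standardizers are available: `"change_sd"` uses the SD of
#' the change scores computed from both SDs and r, and
#' `"pooled_prepost"` uses the pooled pre+post SD without the correlation
#' term. The CI uses the normal approximation with
#' `SE = sqrt(2 * (1 - r) / n + d^2 / (2 * n))`.
#'
#' @param summary An [arm_summary()].
#' @param standardizer `"change_corr"` (default), `"change_sd"` or
#'   `"pooled_prepost"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An `effect_size_result`.
#' @examples
#' single_group_effect(arm_summary(99, 50.4, 21.4, 81.8, 17.7, 0.335))
#' @export
single_group_effect <- function(summary,
                                standardizer = c("change_corr", "change_sd",
                                                 "pooled_prepost"),
                                conf_level = 0.95) {
  stopifnot(inherits(summary, "arm_summary"))
  standardizer <- match.arg(standardizer)
  s <- summary
  if (standardizer != "pooled_prepost" && s$r >= 1) {
    stop("r = 1 gives a zero-variance change score", call. = FALSE)
  }
  denom <- switch(standardizer,
    change_corr = s$pre_sd * sqrt(2 * (1 - s$r)),
    change_sd = sqrt(s$pre_sd^2 + s$post_sd^2 -
                       2 * s$r * s$pre_sd * s$post_sd),
    pooled_prepost = sqrt((s$pre_sd^2 + s$post_sd^2) / 2))
  d <- (s$post_mean - s$pre_mean) / denom
  se <- sqrt(2 * (1 - s$r) / s$n + d^2 / (2 * s$n))
  z <- qnorm(1 - (1 - conf_level) / 2)
  effect_size_result(d, d - z * se, d + z * se, correction = 1,
                     method = paste0("single_group_", standardizer),
                     conf_level = conf_level)
}

#' Pretest-posttest-control effect size (Morris G)
#'
#' The between-arm standardized mean difference of pre-to-post change:
#' `g = c * (delta_T - delta_C) / SD_pooled`, where `delta` is each arm's
#' mean change and `c` is a small-sample bias-correction factor. The
#' default pooling forms the pooled SD from all four pre/post cells
#' weighted by their degrees of freedom (pre/post variances are assumed
#' homogeneous); `pooling = "pretest_only"` pools the two pretest SDs,
#' matching the classic Morris (2008) estimator. The CI uses the Morris
#' (2008) variance approximation with the n-weighted average pre/post
#' correlation and normal quantiles.
#'
#' @param treatment,control [arm_summary()] objects.
#' @param correction Small-sample correction factor c. The default 0.998
#'   is the constant used in the emulated study; pass `NULL` to compute
#'   `1 - 3 / (4 * df - 1)` from the pooling degrees of freedom.
#' @param pooling `"all_cells"` (default) or `"pretest_only"`.
#' @param conf_level Confidence level.
#' @return An `effect_size_result`.
#' @examples
#' trt <- arm_summary(99, 50.4, 21.4, 81.8, 17.7, 0.335)
#' ctl <- arm_summary(148, 56.1, 23.2, 85.8, 15.6, 0.226)
#' morris_g(trt, ctl)
#' @export
morris_g <- function(treatment, control, correction = 0.998,
                     pooling = c("all_cells", "pretest_only"),
                     conf_level = 0.95) {
  stopifnot(inherits(treatment, "arm_summary"),
            inherits(control, "arm_summary"))
  pooling <- match.arg(pooling)
  tr <- treatment; ct <- control
  if (pooling == "all_cells") {
    v <- c(tr$pre_sd, tr$post_sd, ct$pre_sd, ct$post_sd)^2
    df <- c(tr$n - 1, tr$n - 1, ct$n - 1, ct$n - 1)
  } else {
    v <- c(tr$pre_sd, ct$pre_sd)^2
    df <- c(tr$n - 1, ct$n - 1)
  }
  sd_pooled <- sqrt(sum(v * df) / sum(df))
  if (sd_pooled <= 0) stop("degenerate pooled SD", call. = FALSE)
  if (is.null(correction)) {
    correction <- 1 - 3 / (4 * sum(df) - 1)
  }
  delta <- (tr$post_mean - tr$pre_mean) - (ct$post_mean - ct$pre_mean)
  g <- correction * delta / sd_pooled
  nT <- tr$n; nC <- ct$n; N <- nT + nC
  rbar <- (nT * tr$r + nC * ct$r) / N
  base <- 2 * (1 - rbar) * (1 / nT + 1 / nC)
  vg <- correction^2 * base * ((N - 2) / (N - 4)) *
    (1 + g^2 / base) - g^2
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(max(vg, 0))
  res <- effect_size_result(g, g - z * se, g + z * se, correction,
                            method = paste0("morris_g_", pooling),
                            conf_level = conf_level)
  res$sd_pooled <- sd_pooled
  res
}

#' Export effect-size results as YAML
#'
#' @param results Named list of `effect_size_result` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_effect_sizes <- function(results, path) {
  if (inherits(results, "effect_size_result")) results <- list(results)
  yaml::write_yaml(lapply(results, function(r) {
    list(estimate = r$estimate, ci_low = r$ci_low, ci_high = r$ci_high,
         correction = r$correction, method = r$method,
         conf_level = r$conf_level)
  }), path)
  invisible(path)
}
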