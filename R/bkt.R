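#' Bayesian Knowledge Tracing parameters
#'
#' Bundles the four parameters of the classic two-state BKT learner model:
#' the prior probability of mastery at the first opportunity (`p_init`, often
#' written L0), the per-opportunity learning transition (`p_learn`, T), the
#' slip probability (`p_slip`, S: a mastered learner answering incorrectly)
#' and the guess probability (`p_guess`, G: an unmastered learner answering
#' correctly).
#'
#' The usual identifiability constraints are enforced: every parameter lies
#' in `[0, 1]`, and both `p_slip` and `p_guess` must be below 0.5 (which also
#' guarantees `p_slip + p_guess < 1`), so that "knowing" a skill cannot be
#' relabelled as "not knowing" it.
#'
#' @param p_init Prior mastery probability L0.
#' @param p_learn Learning (transition) probability T per opportunity.
#' @param p_slip Slip probability S.
#' @param p_guess Guess probability G.
#' @return An object of class `bkt_params`.
#' @examples
#' bkt_params(0.3, 0.2, 0.1, 0.15)
#' @export
bkt_params <- function(p_init, p_learn, p_slip, p_guess) {
  assert_probability(p_init)
  assert_probability(p_learn)
  assert_probability(p_slip)
  assert_probability(p_guess)
  if (p_slip >= 0.5 || p_guess >= 0.5) {
    stop("`p_slip` and `p_guess` must each be below 0.5 (identifiability)",
         call. = FALSE)
  }
  structure(
    list(p_init = p_init, p_learn = p_learn,
         p_slip = p_slip, p_guess = p_guess),
    class = "bkt_params"
  )
}

#' @export
print.bkt_params <- function(x, ...) {
  cat("<bkt_params>  L0 =", format(x$p_init, digits = 4),
      " T =", format(x$p_learn, digits = 4),
      " S =", format(x$p_slip, digits = 4),
      " G =", format(x$p_guess, digits = 4), "\n")
  if (isTRUE(attr(x, "degenerate"))) {
    cat("  (fit flagged as degenerate: boundary-constrained)\n")
  }
  invisible(x)
}

#' Knowledge state of a traced skill
#'
#' The evolving mastery probability L of one learner on one skill, together
#' with the number of practice opportunities observed so far.
#'
#' @param p_know Current mastery probability L.
#' @param opportunities Number of attempts observed (non-negative integer).
#' @return An object of class `knowledge_state`.
#' @export
knowledge_state <- function(p_know, opportunities = 0L) {
  assert_probability(p_know)
  opportunities <- as.integer(opportunities)
  if (is.na(opportunities) || opportunities < 0L) {
    stop("`opportunities` must be a non-negative integer", call. = FALSE)
  }
  structure(list(p_know = p_know, opportunities = opportunities),
            class = "knowledge_state")
}

#' @export
print.knowledge_state <- function(x, ...) {
  cat("<knowledge_state>  L =", format(x$p_know, digits = 4),
      " after", x$opportunities, "opportunities\n")
  invisible(x)
}

state_prob <- function(state) {
  if (inherits(state, "knowledge_state")) state$p_know
  else assert_probability(state, "state", allow_vector = TRUE)
}

#' Predicted probability of a correct next attempt
#'
#' Under BKT the probability that the next attempt is correct is
#' `L * (1 - S) + (1 - L) * G`: a mastered learner succeeds unless they slip,
#' an unmastered one succeeds only by guessing.
#'
#' @param state A [knowledge_state()] or a numeric mastery probability
#'   (vectorized).
#' @param params A [bkt_params()].
#' @return Probability (or vector of probabilities) of a correct response.
#' @examples
#' predict_correct(knowledge_state(0.6), bkt_params(0.3, 0.2, 0.1, 0.2))
#' @export
predict_correct <- function(state, params) {
  stopifnot(inherits(params, "bkt_params"))
  L <- state_prob(state)
  L * (1 - params$p_slip) + (1 - L) * params$p_guess
}

#' Update a knowledge state after an observed attempt
#'
#' Applies the BKT evidence (Bayes) update for the observed outcome followed
#' by the learning transition: after conditioning on the outcome, the learner
#' may acquire the skill with probability `p_learn`. Intermediate posteriors
#' are clipped away from 0 and 1 so long histories stay numerically stable,
#' but structurally impossible evidence (for example observing a correct
#' answer when both mastery and guessing are exactly zero) is an error.
#'
#' @param state A [knowledge_state()].
#' @param params A [bkt_params()].
#' @param correct Logical/binary outcome of the attempt.
#' @return The updated [knowledge_state()], with `opportunities` incremented.
#' @examples
#' s <- knowledge_state(0.5)
#' update_posterior(s, bkt_params(0.5, 0, 0.1, 0.2), correct = TRUE)
#' @export
update_posterior <- function(state, params, correct) {
  stopifnot(inherits(state, "knowledge_state"),
            inherits(params, "bkt_params"))
  correct <- assert_flag_binary(correct)
  if (length(correct) != 1L) stop("`correct` must be a single flag")
  L <- state$p_know
  S <- params$p_slip
  G <- params$p_guess
  denom <- if (correct == 1L) L * (1 - S) + (1 - L) * G
           else L * S + (1 - L) * (1 - G)
  if (denom == 0) {
    stop("degenerate evidence: observed outcome has probability zero ",
         "under the current state and parameters", call. = FALSE)
  }
  post <- if (correct == 1L) L * (1 - S) / denom else L * S / denom
  post <- clip_prob(post)
  post <- post + (1 - post) * params$p_learn
  knowledge_state(clip_prob(post), state$opportunities + 1L)
}

# vectorized posterior+transition update used by the simulator and the
# filtering likelihood; L and correct are equal-length numeric vectors
bkt_update_vec <- function(L, correct, S, G, T_) {
  pc <- L * (1 - S) + (1 - L) * G
  post <- ifelse(correct == 1, L * (1 - S) / clip_prob(pc),
                 L * S / clip_prob(1 - pc))
  post <- clip_prob(post)
  clip_prob(post + (1 - post) * T_)
}

#' Simulate attempt sequences from a BKT model
#'
#' Draws hidden mastery trajectories and binary outcomes for `n_learners`
#' independent learners, each observed for `n_opportunities` attempts on a
#' single skill. Used for parameter-recovery experiments and calibration.
#'
#' @param params Generating [bkt_params()].
#' @param n_learners Number of independent sequences.
#' @param n_opportunities Attempts per sequence.
#' @param seed Integer seed.
#' @param task_id Skill identifier recorded on every row.
#' @return A tibble with columns `learner_id`, `task_id`,
#'   `opportunity_index`, `correct` (one row per attempt).
#' @export
bkt_simulate <- function(params, n_learners, n_opportunities, seed,
                         task_id = "skill_1") {
  stopifnot(inherits(params, "bkt_params"),
            n_learners >= 1, n_opportunities >= 1)
  set.seed(as.integer(seed))
  know <- matrix(FALSE, n_learners, n_opportunities)
  know[, 1] <- runif(n_learners) < params$p_init
  if (n_opportunities > 1) {
    for (t in 2:n_opportunities) {
      know[, t] <- know[, t - 1] |
        (runif(n_learners) < params$p_learn)
    }
  }
  p_corr <- ifelse(know, 1 - params$p_slip, params$p_guess)
  correct <- matrix(runif(n_learners * n_opportunities), n_learners) < p_corr
  tibble::tibble(
    learner_id = rep(sprintf("L%04d", seq_len(n_learners)),
                     each = n_opportunities),
    task_id = task_id,
    opportunity_index = rep(seq_len(n_opportunities), n_learners),
    correct = as.integer(t(correct))
  )
}

# build an NA-padded outcome matrix (one row per learner x task sequence)
# from long-form attempt data
outcome_matrix <- function(attempts) {
  stopifnot(all(c("learner_id", "task_id", "correct") %in% names(attempts)))
  correct <- assert_flag_binary(attempts$correct, "correct")
  key <- paste(attempts$learner_id, attempts$task_id, sep = "\r")
  if ("opportunity_index" %in% names(attempts)) {
    ord <- order(key, attempts$opportunity_index)
  } else {
    ord <- order(key)
  }
  key <- key[ord]
  correct <- correct[ord]
  seqs <- split(correct, factor(key, levels = unique(key)))
  lens <- lengths(seqs)
  out <- matrix(NA_integer_, length(seqs), max(lens))
  for (i in seq_along(seqs)) out[i, seq_len(lens[i])] <- seqs[[i]]
  out
}

# filtering log-likelihood of an outcome matrix under one parameter set;
# identical to the HMM forward algorithm for this model
bkt_loglik_matrix <- function(O, p_init, p_learn, p_slip, p_guess) {
  n <- nrow(O)
  L <- rep(p_init, n)
  ll <- 0
  for (t in seq_len(ncol(O))) {
    o <- O[, t]
    obs <- which(!is.na(o))
    if (!length(obs)) next
    pc <- clip_prob(L[obs] * (1 - p_slip) + (1 - L[obs]) * p_guess)
    lik <- ifelse(o[obs] == 1, pc, 1 - pc)
    ll <- ll + sum(log(lik))
    L[obs] <- bkt_update_vec(L[obs], o[obs], p_slip, p_guess, p_learn)
  }
  ll
}

#' Log-likelihood of attempt sequences under BKT parameters
#'
#' @param params A [bkt_params()].
#' @param attempts Long-form attempt data (`learner_id`, `task_id`,
#'   optional `opportunity_index`, `correct`).
#' @return Total log-likelihood over all sequences.
#' @export
bkt_loglik <- function(params, attempts) {
  stopifnot(inherits(params, "bkt_params"))
  O <- outcome_matrix(attempts)
  bkt_loglik_matrix(O, params$p_init, params$p_learn,
                    params$p_slip, params$p_guess)
}

# grid log-likelihoods, vectorized over both grid rows and sequences;
# processed in chunks to bound memory
grid_loglik <- function(grid, O, chunk = 4000L) {
  ll <- numeric(nrow(grid))
  for (start in seq(1L, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    g <- grid[idx, , drop = FALSE]
    ng <- nrow(g)
    n <- nrow(O)
    L <- matrix(g$p_init, ng, n)
    acc <- numeric(ng)
    for (t in seq_len(ncol(O))) {
      o <- O[, t]
      obs <- !is.na(o)
      if (!any(obs)) next
      pc <- L * (1 - g$p_slip) + (1 - L) * g$p_guess
      lik <- pc
      zero <- which(!is.na(o) & o == 0)
      if (length(zero)) lik[, zero] <- 1 - pc[, zero]
      acc <- acc + rowSums(log(pmin(pmax(
        lik[, obs, drop = FALSE], .PROB_EPS), 1 - .PROB_EPS)))
      post <- L * g$p_slip / (1 - pc)
      ones <- which(!is.na(o) & o == 1)
      if (length(ones)) {
        post[, ones] <- (L * (1 - g$p_slip) / pc)[, ones]
      }
      post <- pmin(pmax(post, .PROB_EPS), 1 - .PROB_EPS)
      Lnew <- post + (1 - post) * g$p_learn
      L[, obs] <- Lnew[, obs]
    }
    ll[idx] <- acc
  }
  ll
}

# one Baum-Welch EM run from a given start; O is the NA-padded outcome
# matrix with padding only at the tail of each row
bkt_em_run <- function(O, start, tol = 1e-6, max_iter = 500L) {
  lens <- rowSums(!is.na(O))
  n <- nrow(O)
  Tm <- ncol(O)
  L0 <- start[1]; Tr <- start[2]; S <- start[3]; G <- start[4]
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    eU <- ifelse(is.na(O), 1, ifelse(O == 1, G, 1 - G))
    eK <- ifelse(is.na(O), 1, ifelse(O == 1, 1 - S, S))
    aU <- matrix(0, n, Tm); aK <- matrix(0, n, Tm); cs <- matrix(1, n, Tm)
    aU[, 1] <- (1 - L0) * eU[, 1]
    aK[, 1] <- L0 * eK[, 1]
    cs[, 1] <- aU[, 1] + aK[, 1]
    aU[, 1] <- aU[, 1] / cs[, 1]; aK[, 1] <- aK[, 1] / cs[, 1]
    if (Tm > 1) for (t in 2:Tm) {
      obs <- lens >= t
      u <- aU[, t - 1] * (1 - Tr) * eU[, t]
      k <- (aU[, t - 1] * Tr + aK[, t - 1]) * eK[, t]
      ct <- u + k
      aU[, t] <- ifelse(obs, u / ct, aU[, t - 1])
      aK[, t] <- ifelse(obs, k / ct, aK[, t - 1])
      cs[, t] <- ifelse(obs, ct, 1)
    }
    ll <- sum(log(cs[!is.na(O)]))
    bU <- matrix(1, n, Tm); bK <- matrix(1, n, Tm)
    if (Tm > 1) for (t in (Tm - 1):1) {
      obs <- lens >= t + 1
      u <- ((1 - Tr) * eU[, t + 1] * bU[, t + 1] +
              Tr * eK[, t + 1] * bK[, t + 1]) / cs[, t + 1]
      k <- (eK[, t + 1] * bK[, t + 1]) / cs[, t + 1]
      bU[, t] <- ifelse(obs, u, bU[, t + 1])
      bK[, t] <- ifelse(obs, k, bK[, t + 1])
    }
    gK <- aK * bK
    gU <- aU * bU
    mask <- !is.na(O)
    # expected transitions U -> K between t and t+1
    num_T <- 0; den_T <- 0
    if (Tm > 1) for (t in 1:(Tm - 1)) {
      obs <- lens >= t + 1
      xi <- aU[, t] * Tr * eK[, t + 1] * bK[, t + 1] / cs[, t + 1]
      num_T <- num_T + sum(xi[obs])
      den_T <- den_T + sum(gU[obs, t])
    }
    corr <- !is.na(O) & O == 1
    inc <- !is.na(O) & O == 0
    L0 <- min(max(mean(gK[, 1]), 1e-3), 0.999)
    if (den_T > 0) Tr <- min(max(num_T / den_T, 1e-3), 0.999)
    sk <- sum(gK[mask])
    su <- sum(gU[mask])
    if (sk > 0) S <- min(max(sum(gK[inc]) / sk, 1e-3), 0.499)
    if (su > 0) G <- min(max(sum(gU[corr]) / su, 1e-3), 0.499)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(par = c(L0, Tr, S, G), loglik = ll, iterations = iter)
}

#' Fit BKT parameters from attempt sequences
#'
#' Two fitting routes are provided. `method = "grid"` performs an exhaustive
#' search over a 0.05-step lattice (`p_init`, `p_learn` in 0.05..0.95;
#' `p_slip`, `p_guess` in 0.05..0.45, respecting the identifiability
#' constraints) and is intended as a slow, transparent reference.
#' `method = "em"` runs Baum-Welch expectation-maximization with 10 seeded
#' random restarts and a convergence tolerance of 1e-6 on the
#' log-likelihood, keeping the restart with the best likelihood.
#'
#' All supplied sequences are pooled into a single skill; to trace tasks as
#' independent skills, fit per `task_id` subset.
#'
#' @param attempts Long-form attempt data (`learner_id`, `task_id`,
#'   optional `opportunity_index`, `correct`), at least one sequence with at
#'   least two outcomes.
#' @param method `"em"` (default) or `"grid"`.
#' @param seed Integer seed controlling the EM restarts.
#' @return A [bkt_params()] with attributes `loglik`, `method` and
#'   `degenerate` (TRUE when the data carry no contradicting evidence, in
#'   which case the fit sits on the search boundary and a warning is issued).
#' @export
bkt_fit <- function(attempts, method = c("em", "grid"), seed = 1L) {
  method <- match.arg(method)
  O <- outcome_matrix(attempts)
  if (max(rowSums(!is.na(O))) < 2) {
    stop("need at least one sequence with >= 2 outcomes", call. = FALSE)
  }
  vals <- O[!is.na(O)]
  degenerate <- length(unique(vals)) < 2L
  if (degenerate) {
    warning("all outcomes identical: fit is boundary-constrained and ",
            "parameters are not identifiable", call. = FALSE)
  }
  if (method == "grid") {
    lattice <- seq(0.05, 0.95, by = 0.05)
    sg <- seq(0.05, 0.45, by = 0.05)
    grid <- expand.grid(p_init = lattice, p_learn = lattice,
                        p_slip = sg, p_guess = sg)
    ll <- grid_loglik(grid, O)
    best <- which.max(ll)
    fit <- bkt_params(grid$p_init[best], grid$p_learn[best],
                      grid$p_slip[best], grid$p_guess[best])
    attr(fit, "loglik") <- ll[best]
  } else {
    set.seed(as.integer(seed))
    starts <- rbind(
      c(0.4, 0.2, 0.1, 0.2),
      matrix(c(runif(9, 0.05, 0.95), runif(9, 0.05, 0.95),
               runif(9, 0.05, 0.45), runif(9, 0.05, 0.45)), ncol = 4)
    )
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      run <- bkt_em_run(O, starts[i, ])
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
    fit <- bkt_params(best$par[1], best$par[2], best$par[3], best$par[4])
    attr(fit, "loglik") <- best$loglik
  }
  attr(fit, "method") <- method
  attr(fit, "degenerate") <- degenerate
  attr(fit, "n_sequences") <- nrow(O)
  fit
}

#' Read or write attempt sequences as JSONL
#'
#' One JSON object per line with fields `learner_id`, `task_id`,
#' `opportunity_index`, `correct`.
#'
#' @param attempts Long-form attempt tibble.
#' @param path File path.
#' @return `read_attempts()` returns the attempt tibble;
#'   `write_attempts()` returns `path` invisibly.
#' @export
write_attempts <- function(attempts, path) {
  stopifnot(all(c("learner_id", "task_id", "opportunity_index", "correct")
                %in% names(attempts)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(attempts))) {
    writeLines(jsonlite::toJSON(as.list(attempts[i, ]), auto_unbox = TRUE),
               con)
  }
  invisible(path)
}

#' @rdname write_attempts
#' @export
read_attempts <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
  tibble::tibble(
    learner_id = vapply(rows, `[[`, "", "learner_id"),
    task_id = vapply(rows, `[[`, "", "task_id"),
    opportunity_index = vapply(rows, function(r)
      as.integer(r$opportunity_index), 1L),
    correct = vapply(rows, function(r) as.integer(r$correct), 1L)
  )
}

#' Serialize BKT parameters to/from YAML
#'
#' @param params A [bkt_params()].
#' @param path File path.
#' @return `read_bkt_params()` returns a [bkt_params()];
#'   `write_bkt_params()` returns `path` invisibly.
#' @export
write_bkt_params <- function(params, path) {
  stopifnot(inherits(params, "bkt_params"))
  yaml::write_yaml(unclass(params)[c("p_init", "p_learn",
                                     "p_slip", "p_guess")], path)
  invisible(path)
}

#' @rdname write_bkt_params
#' @export
read_bkt_params <- function(path) {
  x <- yaml::read_yaml(path)
  bkt_params(x$p_init, x$p_learn, x$p_slip, x$p_guess)
}
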