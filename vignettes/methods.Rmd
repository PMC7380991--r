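---
title: "Models and methods behind bktrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bktrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bktrial)
```

bktrial studies a specific experimental setting: a two-arm randomized
trial of adaptive versus standardized feedback inside a smartphone-based
clinical training game, where learners self-schedule their repeat
sessions and a learner model decides how much feedback detail to show.
This vignette documents the models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic-data generator
can and cannot stand in for.

## The learner model

Each learning task is traced as an independent skill by standard Bayesian
Knowledge Tracing: a two-state hidden Markov model in which the learner
either knows the skill or not. Four probabilities govern it: prior
mastery `p_init` (L0), the per-opportunity learning transition `p_learn`
(T), slip `p_slip` (S) and guess `p_guess` (G). Observing an outcome
updates mastery by Bayes' rule; the learning transition is applied after
the evidence update. The model deliberately contains no forgetting —
forgetting enters only *between* sessions, in the simulator — and both
S and G are constrained below 0.5 so that mastery and its complement
cannot be relabelled into one another.

Two fitting routes are provided and cross-check one another:

* **Grid search** over a 0.05-step lattice (`p_init`, `p_learn` in
  0.05–0.95; `p_slip`, `p_guess` in 0.05–0.45). Transparent and exhaustive;
  used as the reference in tests.
* **EM (Baum–Welch)** with 10 random restarts under a fixed seed and a
  convergence tolerance of 1e-6 on the log-likelihood. Restarts matter
  because BKT likelihoods are multimodal; the best restart is kept.

The lattice bounds are a documented package choice: the slip/guess cap at
0.45 keeps the search inside the identifiable region, and 0.05 steps make
the grid (19 × 19 × 9 × 9 points) exhaustive within seconds at the data
sizes used here. Degenerate data (all outcomes identical) cannot identify
the parameters; the fit is returned at the search boundary with a warning
flag rather than an error, since downstream code may still want the
boundary likelihood.

Intermediate posteriors are clipped to [1e-9, 1 − 1e-9] so that long
histories at extreme parameters cannot produce 0/0; structurally
impossible evidence (an outcome with probability exactly zero under the
current state) is still raised as an error rather than silently clipped.

## The feedback policy

Feedback is emitted on every incorrect attempt. The control arm is fixed:
a minimal retry prompt (level 0) on the first incorrect attempt and the
detailed explanation (level 2) from the second onward — repeated for
attempts beyond the second, which the deployed cascade left unspecified.
The adaptive arm maps the predicted probability of next-attempt success,
computed *after* the posterior update for the just-observed failure, onto
three levels: minimal at or above `tau_high`, reflective between the
thresholds, detailed below `tau_low`. Ties go to the less detailed level
(the comparisons are `>=`), making the mapping monotone non-increasing in
the prediction.

The deployed thresholds were never published. The defaults (0.70, 0.85)
were chosen jointly with the calibrated learning rate: after a failure the
predicted success probability clusters around 0.65–0.75, so these cutoffs
make all three levels actually occur in simulated logs, with detailed
feedback dominating for weaker learners. Both thresholds are plain
configuration (`trial_config()`, `feedback_policy()`, `--thresholds`).

Message texts are deterministic placeholder templates: the reflective
level references the number of wrong choices and the scenario stage
without revealing answers, the detailed level enumerates the incorrect
choices and appends a per-stage explanation. The clinical wording of the
deployed content is out of scope.

## The trial simulator

`simulate_trial()` generates the full trial: population, allocation,
sessions, spacing, forgetting, dropout.

* **Allocation** follows the in-app scheme: an integer draw in {0,1,2,3},
  0/1 recoded to control and 2/3 to experiment. The observed trial ended
  up imbalanced (~60:40 among completers) because of a platform-dependent
  RNG deficiency; this is modelled as a configurable allocation
  probability (default 0.40 toward the experiment arm) rather than by
  emulating a faulty generator, whose behaviour is unknowable.
* **Covariates** (cadre, training level, age, experience, prior exposure
  to the emergency-care curriculum) are drawn from the baseline
  frequencies of the emulated study's background table.
* **Ability** (per-learner L0) is Beta-distributed per arm. The arm means
  differ because the emulated trial's arms happened to differ at baseline;
  reproducing that imbalance is part of reproducing the study conditions.
* **Sessions** play every task until correct or an attempt cap (default
  5, guaranteeing termination); each failure emits feedback, and reading
  a message can itself raise mastery (`feedback_uptake`, one probability
  per level). The session score is 100 × the fraction of tasks correct on
  the first attempt.
* **Spacing** between sessions is a categorical mixture over the four
  bins used in the analysis (≤1 hour, ≤1 day, ≤1 week, ≤1 month), uniform
  within each bin.
* **Forgetting** decays each task's mastery toward the learner's prior,
  `L' = p_init + (L - p_init) exp(-λ · days)`, so longer gaps never help
  and mastery never falls below its prior.
* **Dropout** is independent Bernoulli per round (default retention
  0.432, the completer fraction observed in the emulated trial; the
  protocol's planning assumption of 50% is one keystroke away). A
  covariate-dependent variant raises dropout for clinical officers and
  specialized-trained learners, mirroring the attrition pattern reported
  there.

### Calibration of the defaults

The defaults are calibrated so that the simulated trial reproduces the
emulated study's arm-level score moments: pretest means near 56
(control) and 50 (experiment) with SDs near 22, posttest means in the
low-to-mid 80s with SDs near 16–18, pre/post correlations around
0.2–0.35, and a completer count near 43% of 572 enrolled. The moving
parts interact — the learning rate and feedback uptake set the
within-session mastery endpoint, the forgetting rate and spacing mixture
set both the posttest mean and its spread, and the slip probability sets
the attainable ceiling — so the calibration was done once, jointly, and
frozen: `p_learn = 0.60`, `p_slip = 0.02`, `p_guess = 0.20`,
`forgetting_rate = 0.09`/day, spacing mixture (0.33, 0.27, 0.22, 0.18),
ability means 0.472/0.385 with SD 0.25, uptake (0, 0.25, 0.40). The
ability means sit slightly above what the pretest means alone would
imply because learners with a perfect pretest have no headroom for a
normalized gain and are excluded from gain analyses, which shifts the
analyzed pretest mean down.

Scores are means of 12 Bernoulli tasks (the scenario's true task count is
unpublished; 12 is the package default), so a single simulated trial of
572 learners carries sampling noise of roughly ±1.5–2 points per arm
mean; the calibration test therefore averages 10 replicates.

### What the generator does and does not emulate

It emulates the *structure* of the study: arm imbalance, covariate
marginals, score distributions, spacing-dependent gains, per-round
attrition, and the structural zero of reflective messages in the control
arm. It does not emulate: country-level recruitment skew, the app-store
distribution funnel, the actual feedback prose, correlations between
covariates and ability (covariates are drawn independently of ability by
default), or the real trial's message volumes per learner. Tests passing
on synthetic data therefore validate the computational pipeline and its
statistical calibration — not claims about any real cohort.

## Effect sizes

**Single-group pre/post.** The default standardizer divides the mean
change by `SD_pre * sqrt(2(1 - r))` — the change-score SD implied by the
pretest SD under equal pre/post variances. This choice reproduces the
emulated study's published per-arm effect sizes from its published
summary statistics, which is how the convention was identified; the
change-score SD computed from both SDs and the pooled pre+post SD are
available behind `standardizer=`. The CI uses
`SE = sqrt(2(1 - r)/n + d²/(2n))` with normal quantiles.

**Morris G.** The between-arm standardized difference of mean changes.
The default pools all four pre/post variances weighted by their degrees
of freedom — consistent with the homogeneity assumption stated for the
design and with the published headline value at two decimals; pooling the
pretest SDs alone (the classic estimator) is available and gives a
slightly smaller value. The small-sample correction defaults to the
published constant 0.998, because the degrees-of-freedom convention
behind it is not recoverable (plausible df choices give 0.997–0.998);
passing `correction = NULL` derives `1 - 3/(4 df - 1)` from the pooling
df instead. The CI uses the Morris (2008) variance approximation with the
n-weighted average pre/post correlation and normal quantiles.

Records with a perfect pretest are excluded from gain analyses (the
normalized gain `(post - pre)/(100 - pre)` is undefined there) and
reported in a QC table; negative gains are retained as computed.

## Regression, attrition and variance tests

The gain regression is plain OLS with dummy coding against declared
reference levels (spacing ≤1 hour, control arm, nurse cadre, student
level) and no multiple-testing adjustment, reporting per-term 95% CIs,
adjusted R², the Breusch–Pagan p-value and VIFs. Continuous predictors
(time on task, age, experience) are z-standardized by default: the
emulated study's coefficient scale for age and experience is consistent
with standardized inputs, and the choice is recorded in the fitted
object. Exact collinearity is a named error listing the aliased terms
rather than a silently dropped column.

Attrition comparisons use the Welch unequal-variance t-test for
continuous variables (the variant is not named in the emulated study;
Welch is the safer default) and per-level two-proportion z-tests without
continuity correction (a corrected variant is a flag). Variance
homogeneity uses the Brown–Forsythe (median-centered) Levene variant by
default for robustness to non-normality.

## Power and sample size

`required_sample_size()` solves the noncentral-t power equation for the
minimal total n. For the paired/one-sample design the per-group count is
`ceiling(total / 2)` — the convention for a two-arm trial whose endpoint
analysis is within-subject: at d = 0.22, α = .05 two-sided and 80% power
the equation gives 164.1, hence a total of 165 and 83 per group. The
normal-approximation mode (`(z_{1-α/2} + z_{power})²/d²` ≈ 162.2 before
rounding) is kept for reference. `power_simulation()` estimates power as
a Monte-Carlo rejection rate and is used to verify the solver; repeated-
measures designs beyond the paired t are deliberately out of scope, as
the emulated study itself found longitudinal modelling infeasible at its
attrition rates.

## Numerical and interface decisions

* Spacing bins are half-open on the left — exactly one hour is still
  "≤1 hour" — and gaps above 31 days are clamped into the ≤1 month bin
  with a flag rather than dropped.
* Timestamps are ISO-8601 UTC; spacing is measured from end of session 1
  to start of session 2.
* Event logs are schema-versioned JSONL (one session per line, nested
  attempts) or an equivalent flattened CSV; malformed rows become a
  rejects table with line numbers instead of aborting the parse, but a
  schema version mismatch is a hard error. `analyze` refuses logs that
  fail validation.
* Every CLI invocation writes a manifest (seed, config hash, package
  version, paths) sufficient to reproduce its outputs byte-identically.
* All simulation entry points take explicit integer seeds; identical
  config and seed reproduce logs byte-for-byte.

## Problem sizes used by the test suite

The suite exercises the statistical claims at sizes chosen to keep the
whole run in the low minutes while leaving comfortable Monte-Carlo
margins: BKT recovery at 500 learners × 12 opportunities (±0.05
tolerance), grid-vs-EM agreement at 200 learners, regression recovery and
null coverage at n = 250 × 500 replicates, Morris G null coverage at 500
replicates of a 148/99 split, power simulation at 20,000 replicates, and
simulator calibration as a 10-replicate average of the default 572-learner
trial.

## Known limitations

* Single shared BKT parameter set per trial (ability varies per learner,
  S/G/T do not); the deployed model's sharing across cadres is unknown.
* Covariates are independent of ability and of each other, so the gain
  regression's covariate terms are null in default simulations.
* The Morris G confidence interval is a normal-theory approximation; the
  emulated study's exact CI construction is not recoverable.
* The generator's feedback volumes are policy-consistent but not
  calibrated to the published message counts.
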