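#' Regression specification for gain models
#'
#' Declares the response, the predictors in order, the reference level of
#' each categorical predictor (spacing `<=1 hour`, arm `control`, cadre
#' `nurse`, training level `student`, prior curriculum exposure `no`), and
#' which continuous predictors are z-standardized before fitting.
#'
#' @param response Response column (default `"gain"`).
#' @param predictors Character vector of predictor columns, in order.
#' @param references Named list/character of reference levels for
#'   categorical predictors.
#' @param standardize Character vector of continuous predictors to
#'   z-standardize.
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(response = "gain",
                            predictors = c("spacing", "arm",
                                           "time_on_task", "help_ratio",
                                           "prior_etat"),
                            references = c(spacing = "<=1 hour",
                                           arm = "control",
                                           cadre = "nurse",
                                           level = "student"),
                            standardize = c("time_on_task", "age",
                                            "experience")) {
  if (anyDuplicated(predictors)) {
    stop("duplicate predictors in specification", call. = FALSE)
  }
  structure(list(response = response, predictors = predictors,
                 references = references, standardize = standardize),
            class = "regression_spec")
}

#' OLS regression of normalized learning gains
#'
#' Fits an ordinary least squares model of the normalized gain on the
#' declared predictors with dummy coding against the declared reference
#' levels, z-standardizing flagged continuous predictors. Reports the
#' coefficient table (estimate, SE, two-sided p, 95% CI), adjusted R^2,
#' the Breusch-Pagan test p-value for homoscedasticity, and variance
#' inflation factors. No multiple-testing adjustment is applied.
#'
#' @param data Gain table (see [gain_table()]) containing the response and
#'   predictor columns.
#' @param spec A [regression_spec()].
#' @return An object of class `gain_regression`: list with `coefficients`
#'   (tibble), `adj_r2`, `bp_pvalue`, `vif`, and the underlying `model`.
#' @export
fit_gain_regression <- function(data, spec = regression_spec()) {
  stopifnot(inherits(spec, "regression_spec"))
  missing_cols <- setdiff(c(spec$response, spec$predictors), names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(data)[, c(spec$response, spec$predictors)]
  df <- df[complete.cases(df), , drop = FALSE]
  n_par <- 1L
  for (p in spec$predictors) {
    x <- df[[p]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      x <- factor(x)
      ref <- if (p %in% names(spec$references)) spec$references[[p]]
             else NULL
      if (!is.null(ref)) {
        if (is.logical(df[[p]])) x <- factor(x, levels = c(FALSE, TRUE))
        else if (ref %in% levels(x)) x <- stats::relevel(x, ref = ref)
      }
      df[[p]] <- x
      n_par <- n_par + nlevels(x) - 1L
    } else {
      if (p %in% spec$standardize) {
        df[[p]] <- as.numeric(scale(x))
      }
      n_par <- n_par + 1L
    }
  }
  if (nrow(df) < n_par + 5L) {
    stop("too few records for the requested model", call. = FALSE)
  }
  form <- stats::reformulate(spec$predictors, response = spec$response)
  fit <- lm(form, data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("singular model matrix; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ci <- confint(fit)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    se = sm$coefficients[, 2],
    p_value = sm$coefficients[, 4],
    ci_low = ci[, 1],
    ci_high = ci[, 2]
  )
  vif <- tryCatch({
    v <- car::vif(fit)
    if (is.matrix(v)) stats::setNames(v[, 1], rownames(v)) else v
  }, error = function(e) NULL)
  structure(list(
    coefficients = coefs,
    adj_r2 = sm$adj.r.squared,
    bp_pvalue = lmtest::bptest(fit)$p.value[[1]],
    vif = vif,
    n = nrow(df),
    model = fit
  ), class = "gain_regression")
}

#' @export
print.gain_regression <- function(x, ...) {
  cat(sprintf("<gain_regression> n=%d  adj R^2=%.3f  Breusch-Pagan p=%.3f\n",
              x$n, x$adj_r2, x$bp_pvalue))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Export a regression coefficient table as CSV
#'
#' @param fit A `gain_regression`.
#' @param path CSV path for the coefficient table.
#' @param diagnostics_path Optional YAML path for adjusted R^2,
#'   Breusch-Pagan p and VIFs.
#' @return `path`, invisibly.
#' @export
write_regression <- function(fit, path, diagnostics_path = NULL) {
  write.csv(fit$coefficients, path, row.names = FALSE)
  if (!is.null(diagnostics_path)) {
    yaml::write_yaml(list(adj_r2 = fit$adj_r2, bp_pvalue = fit$bp_pvalue,
                          vif = as.list(fit$vif), n = fit$n),
                     diagnostics_path)
  }
  invisible(path)
}

#' Welch t-test from summary statistics
#'
#' Two-sided unequal-variance t-test computed from printed group
#' summaries (mean, SD, n), with the Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return A list with `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_summary(31.2, 8.26, 103, 29.4, 6.99, 72)
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  se2 <- sd1^2 / n1 + sd2^2 / n2
  if (se2 == 0) stop("zero variance in both groups", call. = FALSE)
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Two-proportion z-test
#'
#' Difference-in-proportions test using the pooled-variance z statistic,
#' without continuity correction by default.
#'
#' @param x1,n1 Successes and size of group 1.
#' @param x2,n2 Successes and size of group 2.
#' @param continuity Apply the Yates continuity correction.
#' @return A list with `statistic` (z), `p_value`.
#' @export
two_prop_test <- function(x1, n1, x2, n2, continuity = FALSE) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  if (p == 0 || p == 1) {
    return(list(statistic = 0, p_value = 1))
  }
  num <- abs(p1 - p2)
  if (continuity) num <- max(0, num - 0.5 * (1 / n1 + 1 / n2))
  z <- num / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  list(statistic = z, p_value = 2 * pnorm(-z))
}

#' Attrition-bias tests between two baseline tables
#'
#' Compares two groups (for example completers versus dropouts, or the two
#' study arms) variable by variable: continuous variables with the Welch
#' two-sample t-test, categorical variables with per-level two-proportion
#' z-tests (no continuity correction). Variables with zero variance in
#' both groups are skipped with a reason. No multiple-testing adjustment
#' is applied.
#'
#' @param group_a,group_b Data frames with the same baseline columns.
#' @param continuous Character vector of continuous variable names.
#' @param categorical Character vector of categorical variable names.
#' @return A tibble with `variable`, `level`, `type`, `statistic`,
#'   `p_value`, `note`.
#' @export
attrition_tests <- function(group_a, group_b,
                            continuous = c("age", "experience"),
                            categorical = c("cadre", "level",
                                            "prior_etat")) {
  out <- list()
  for (v in intersect(continuous, intersect(names(group_a),
                                            names(group_b)))) {
    a <- group_a[[v]][!is.na(group_a[[v]])]
    b <- group_b[[v]][!is.na(group_b[[v]])]
    if (length(a) < 2 || length(b) < 2) {
      out[[length(out) + 1L]] <- tibble::tibble(
        variable = v, level = NA_character_, type = "welch_t",
        statistic = NA_real_, p_value = NA_real_,
        note = "skipped: fewer than 2 observations per group")
      next
    }
    if (var(a) == 0 && var(b) == 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        variable = v, level = NA_character_, type = "welch_t",
        statistic = NA_real_, p_value = NA_real_,
        note = "skipped: zero variance")
      next
    }
    tt <- t.test(a, b)
    out[[length(out) + 1L]] <- tibble::tibble(
      variable = v, level = NA_character_, type = "welch_t",
      statistic = unname(tt$statistic), p_value = tt$p.value,
      note = NA_character_)
  }
  for (v in intersect(categorical, intersect(names(group_a),
                                             names(group_b)))) {
    a <- group_a[[v]][!is.na(group_a[[v]])]
    b <- group_b[[v]][!is.na(group_b[[v]])]
    levs <- sort(unique(c(as.character(a), as.character(b))))
    for (lv in levs) {
      tp <- two_prop_test(sum(a == lv), length(a),
                          sum(b == lv), length(b))
      out[[length(out) + 1L]] <- tibble::tibble(
        variable = v, level = lv, type = "two_prop_z",
        statistic = tp$statistic, p_value = tp$p_value,
        note = NA_character_)
    }
  }
  dplyr::bind_rows(out)
}

#' Variance-homogeneity test (Brown-Forsythe / Levene)
#'
#' Tests equality of group variances via Levene's procedure. The default
#' centers on group medians (the Brown-Forsythe variant, robust to
#' non-normality); mean centering gives the classic Levene test.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @param center `"median"` (default) or `"mean"`.
#' @return A list with `statistic` (W), `df`, `p_value`, `center`.
#' @export
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("each group needs at least two values", call. = FALSE)
  }
  centerfun <- if (center == "median") stats::median else mean
  tab <- car::leveneTest(values, groups, center = centerfun)
  list(statistic = tab[1, "F value"],
       df = c(tab[1, "Df"], tab[2, "Df"]),
       p_value = tab[1, "Pr(>F)"],
       center = center)
}

#' Power/sample-size specification
#'
#' @param effect_size Standardized effect size d (> 0 for sample-size
#'   solving).
#' @param alpha Two-sided significance level, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param design `"one_sample"`, `"paired"`, `"two_sample"` or
#'   `"anova_oneway"`.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(effect_size = 0.22, alpha = 0.05, power = 0.80,
                       design = c("one_sample", "paired", "two_sample",
                                  "anova_oneway")) {
  design <- match.arg(design)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("`power` must be in (0, 1)")
  structure(list(effect_size = effect_size, alpha = alpha, power = power,
                 design = design),
            class = "power_spec")
}

#' Required sample size for a standardized effect
#'
#' Solves the noncentral-t power equation for the minimal total sample
#' size achieving the target power at the given two-sided level, rounding
#' the total up. For the one-sample and paired designs the per-group count
#' is reported as `ceiling(total / 2)`, the convention used when the total
#' is split over two arms reaching the endpoint. The two-sample design
#' reports the per-group size directly, and `"anova_oneway"` solves the
#' noncentral-F equation for two groups (Cohen's f = d / 2). A normal-
#' approximation mode is available for reference.
#'
#' @param spec A [power_spec()] with `effect_size > 0`.
#' @param method `"noncentral_t"` (default) or `"normal_approx"`.
#' @return A list with `per_group`, `total` and the unrounded `n_exact`.
#' @examples
#' required_sample_size(power_spec(0.22, 0.05, 0.80, "one_sample"))
#' @export
required_sample_size <- function(spec,
                                 method = c("noncentral_t",
                                            "normal_approx")) {
  stopifnot(inherits(spec, "power_spec"))
  method <- match.arg(method)
  d <- spec$effect_size
  if (d <= 0) stop("effect size must be positive; power unreachable",
                   call. = FALSE)
  if (method == "normal_approx") {
    n1 <- (qnorm(1 - spec$alpha / 2) + qnorm(spec$power))^2 / d^2
    n_exact <- switch(spec$design,
                      one_sample = n1, paired = n1,
                      two_sample = 2 * n1, anova_oneway = 2 * n1)
    if (spec$design %in% c("one_sample", "paired")) {
      total <- as.integer(ceiling(n_exact))
      return(list(per_group = as.integer(ceiling(total / 2)),
                  total = total, n_exact = n_exact))
    }
    total <- as.integer(2 * ceiling(n_exact / 2))
    return(list(per_group = total %/% 2L, total = total,
                n_exact = n_exact))
  }
  if (spec$design %in% c("one_sample", "paired")) {
    n_exact <- power.t.test(delta = d, sd = 1, sig.level = spec$alpha,
                            power = spec$power, type = "one.sample")$n
    total <- as.integer(ceiling(n_exact))
    list(per_group = as.integer(ceiling(total / 2)), total = total,
         n_exact = n_exact)
  } else if (spec$design == "two_sample") {
    n_exact <- power.t.test(delta = d, sd = 1, sig.level = spec$alpha,
                            power = spec$power, type = "two.sample")$n
    per_group <- as.integer(ceiling(n_exact))
    list(per_group = per_group, total = 2L * per_group, n_exact = n_exact)
  } else {
    f2 <- (d / 2)^2
    pow <- function(N) {
      pf(qf(1 - spec$alpha, 1, N - 2), 1, N - 2, ncp = N * f2,
         lower.tail = FALSE)
    }
    N <- 8L
    while (pow(N) < spec$power) N <- N + 1L
    list(per_group = as.integer(ceiling(N / 2)), total = N, n_exact = N)
  }
}

#' Monte-Carlo power of the design's test
#'
#' Estimates power as the rejection rate of the design's two-sided t-test
#' at level `alpha` over `reps` simulated replicates with a standardized
#' mean shift of `effect_size` (unit SD). Reproducible given a seed.
#'
#' @param spec A [power_spec()].
#' @param n Sample size (per group for the two-sample design, total for
#'   one-sample/paired).
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return A list with `power`, `mc_se` (binomial Monte-Carlo standard
#'   error), `reps` and `n`.
#' @export
power_simulation <- function(spec, n, reps = 20000L, seed = 1L) {
  stopifnot(inherits(spec, "power_spec"), reps >= 1)
  set.seed(as.integer(seed))
  d <- spec$effect_size
  alpha <- spec$alpha
  if (spec$design %in% c("one_sample", "paired")) {
    x <- matrix(rnorm(n * reps, mean = d), nrow = n)
    m <- colMeans(x)
    s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
    tstat <- sqrt(n) * m / s
    reject <- abs(tstat) > qt(1 - alpha / 2, df = n - 1)
  } else {
    x <- matrix(rnorm(n * reps, mean = d), nrow = n)
    y <- matrix(rnorm(n * reps, mean = 0), nrow = n)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- (colSums(x^2) - n * mx^2) / (n - 1)
    vy <- (colSums(y^2) - n * my^2) / (n - 1)
    se2 <- vx / n + vy / n
    tstat <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / n)^2 / (n - 1))
    reject <- abs(tstat) > qt(1 - alpha / 2, df = df)
  }
  p <- mean(reject)
  list(power = p, mc_se = sqrt(p * (1 - p) / reps),
       reps = as.integer(reps), n = as.integer(n))
}
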