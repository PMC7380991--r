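#' @importFrom stats pf pnorm pt qf qnorm qt rbinom rnorm runif sd var
#' @importFrom stats coef confint cor lm model.matrix p.adjust rlnorm t.test
#' @importFrom stats power.t.test prop.test rbeta setNames complete.cases
#' @importFrom utils head packageVersion write.csv read.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_probability <- function(x, name = deparse(substitute(x)),
                               allow_vector = FALSE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L)) {
    stop(sprintf("`%s` must be a %snumeric probability", name,
                 if (allow_vector) "" else "single "), call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_flag_binary <- function(x, name = deparse(substitute(x))) {
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop(sprintf("`%s` must be strictly binary (0/1)", name), call. = FALSE)
  }
  x
}

# probabilities are clipped before forming Bayes ratios so that degenerate
# parameter corners cannot produce 0/0 during long simulated histories
.PROB_EPS <- 1e-9

clip_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

parse_iso8601 <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
}
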