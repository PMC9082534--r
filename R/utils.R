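# Internal numerical helpers shared across modules.

# Clip probabilities away from {0,1} before logit/cloglog transforms.
# No boundary risk occurs for finite linear predictors, but file-supplied
# risks might sit exactly on the boundary.
clip_prob <- function(p, eps = 1e-10) {
  pmin(pmax(p, eps), 1 - eps)
}

# Complementary log-log link and its inverse: eta = log(-log(1 - p)).
cloglog <- function(p) log(-log(1 - p))
inv_cloglog <- function(eta) 1 - exp(-exp(eta))

#' Wilson score interval for a binomial proportion
#'
#' Used for the sensitivity/specificity/PPV/NPV intervals in threshold
#' tables. Behaves sensibly at boundary counts (0 or n successes), unlike
#' the Wald interval.
#'
#' @param x Number of successes.
#' @param n Number of trials. `n = 0` yields an `NA` estimate and interval.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, level > 0, level < 1)
  if (n == 0) {
    return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp against float rounding: the score interval always contains p
  c(estimate = p,
    lower = min(p, max(0, centre - half)),
    upper = max(p, min(1, centre + half)))
}

# Consistent stop() with a class so tests can assert on error types.
oxrecal_error <- function(msg, class) {
  stop(structure(class = c(class, "oxrecal_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
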