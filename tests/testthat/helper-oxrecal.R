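# Shared test fixtures, built in code.

sweden_coefs <- function() oxrec_coefs("sweden-synthetic")
tajik_coefs <- function() oxrec_coefs("tajikistan-recalibrated")

# Minimal schema for hand-computable cases: one binary predictor.
tiny_schema <- function() {
  predictor_schema(predictor_def("x", "binary"))
}

tiny_coefs <- function(beta = 0.5, S = 0.7992, lambda = 1, imputed = list()) {
  coefficient_set(tiny_schema(), S, list(x = beta),
                  recalibration_shape = lambda, imputed_terms = imputed,
                  label = "tiny")
}

tiny_cohort <- function(x, outcome = NULL) {
  df <- data.frame(id = sprintf("t%03d", seq_along(x)), x = x,
                   stringsAsFactors = FALSE)
  if (!is.null(outcome)) {
    df$outcome <- outcome
    df$outcome_available <- TRUE
  }
  df
}

# A record sitting at every reference level of the default schema.
reference_record <- function() {
  data.frame(id = "ref1", sex = "male", age_band = "a18_29",
             length_of_incarceration = "lt6m", violent_index_offense = 0L,
             previous_violent_crime = 0L, civil_status = "other",
             education = "lt9y", employment = 0L, income = "low",
             alcohol_misuse = 0L, drug_misuse = 0L, any_mental_disorder = 0L,
             any_severe_mental_disorder = 0L, stringsAsFactors = FALSE)
}

# Calibrated synthetic validation cohort: predictors from the Tajik
# marginals, outcomes from the model itself.
calibrated_cohort <- function(n, coefs = sweden_coefs(), seed = 1) {
  coh <- sample_cohort(cohort_spec(n, seed = seed))
  simulate_outcomes(coh, coefs, seed = seed + 10000L)
}

# Brute-force all-pairs concordance oracle for the AUC.
auc_pairs_oracle <- function(scores, outcomes) {
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

# Trapezoidal ROC-area oracle.
auc_trapezoid_oracle <- function(scores, outcomes) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(cuts, function(t) mean(scores[outcomes == 1] >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(scores[outcomes == 0] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}
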