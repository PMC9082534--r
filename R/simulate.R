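#' Predictor marginals of the Tajik validation cohort
#'
#' Marginal distributions for the default schema, taken from the validation
#' study's baseline table (n = 970): 13% female (124/970), length of
#' incarceration 3/13/122/832 across the four bands, 63% violent index
#' offense (608/970), 8% previous violent crime (76/970), 40% unmarried
#' (392/970), education 57/784/129, 64% employed (625/970), 56% stable
#' income (547/970), 37% alcohol misuse (358/970), 9% drug misuse (84/970),
#' 48% any mental disorder (470/970), 5% any severe mental disorder (44/970).
#' Age bands are chosen to match the reported median 35 (IQR 28-43), which
#' the table gives only as summary statistics.
#'
#' Categorical predictors map to a named probability vector over their
#' levels; binary predictors map to the probability of 1.
#'
#' @return Named list of marginals keyed by predictor name.
#' @export
tajik_marginals <- function() {
  n <- 970
  list(
    sex = c(male = 846 / n, female = 124 / n),
    age_band = c(a18_29 = 0.30, a30_39 = 0.35, a40_49 = 0.25, a50plus = 0.10),
    length_of_incarceration = c(lt6m = 3 / n, m6_12 = 13 / n,
                                m12_24 = 122 / n, ge24m = 832 / n),
    violent_index_offense = 608 / n,
    previous_violent_crime = 76 / n,
    civil_status = c(other = 578 / n, unmarried = 392 / n),
    education = c(lt9y = 57 / n, y9_11 = 784 / n, ge12y = 129 / n),
    employment = 625 / n,
    income = c(low = 423 / n, stable = 547 / n),
    alcohol_misuse = 358 / n,
    drug_misuse = 84 / n,
    any_mental_disorder = 470 / n,
    any_severe_mental_disorder = 44 / n
  )
}

#' Approximate predictor marginals of the Swedish derivation cohort
#'
#' The derivation cohort's published percentages, collapsed onto the
#' validation schema (its five income bands are merged into low/stable, so
#' the preset is approximate). Age bands approximate median 36 (IQR 27-46).
#'
#' @return Named list of marginals keyed by predictor name.
#' @export
sweden_marginals <- function() {
  list(
    sex = c(male = 0.93, female = 0.07),
    age_band = c(a18_29 = 0.30, a30_39 = 0.30, a40_49 = 0.22, a50plus = 0.18),
    length_of_incarceration = c(lt6m = 0.69, m6_12 = 0.16, m12_24 = 0.10,
                                ge24m = 0.05),
    violent_index_offense = 0.38,
    previous_violent_crime = 0.53,
    civil_status = c(other = 0.35, unmarried = 0.65),
    education = c(lt9y = 0.48, y9_11 = 0.46, ge12y = 0.06),
    employment = 0.25,
    income = c(low = 0.59, stable = 0.41),
    alcohol_misuse = 0.22,
    drug_misuse = 0.23,
    any_mental_disorder = 0.22,
    any_severe_mental_disorder = 0.03
  )
}

#' Describe a synthetic cohort
#'
#' @param n Number of individuals, at least 1.
#' @param marginals Named list as returned by [tajik_marginals()]; each
#'   categorical marginal must sum to 1 (tolerance 1e-9), each binary
#'   marginal must lie in \[0, 1\].
#' @param seed Integer seed; all randomness flows from it.
#' @param schema Predictor schema, default [oxrec_schema()].
#' @return An object of class `oxrecal_cohort_spec`.
#' @export
cohort_spec <- function(n, marginals = tajik_marginals(), seed = 1,
                        schema = oxrec_schema()) {
  if (n < 1) oxrecal_error("n must be at least 1", "oxrecal_config_error")
  for (nm in names(marginals)) {
    d <- schema[[nm]]
    if (is.null(d)) {
      oxrecal_error(sprintf("marginal for unknown predictor '%s'", nm),
                    "oxrecal_config_error")
    }
    m <- marginals[[nm]]
    if (d$kind == "categorical") {
      if (!setequal(names(m), d$levels) || abs(sum(m) - 1) > 1e-9 || any(m < 0)) {
        oxrecal_error(sprintf("marginal for '%s' must be probabilities over %s summing to 1",
                              nm, paste(d$levels, collapse = "/")),
                      "oxrecal_config_error")
      }
    } else if (length(m) != 1L || m < 0 || m > 1) {
      oxrecal_error(sprintf("marginal for '%s' must be a single probability", nm),
                    "oxrecal_config_error")
    }
  }
  missing <- setdiff(required_predictors(schema), names(marginals))
  if (length(missing)) {
    oxrecal_error(sprintf("no marginal supplied for required predictor(s): %s",
                          paste(missing, collapse = ", ")),
                  "oxrecal_config_error")
  }
  structure(list(n = as.integer(n), marginals = marginals,
                 seed = as.integer(seed), schema = schema),
            class = "oxrecal_cohort_spec")
}

#' Sample a synthetic predictor table
#'
#' Draws each predictor independently from its marginal (the baseline table
#' reports only marginals, so no correlation structure is imposed).
#' Deterministic for a fixed seed.
#'
#' @param spec An `oxrecal_cohort_spec`.
#' @return A cohort data frame (no outcome column yet).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "oxrecal_cohort_spec"))
  n <- spec$n
  withr::with_seed(spec$seed, {
    cols <- list(id = sprintf("id%06d", seq_len(n)))
    for (nm in names(spec$marginals)) {
      d <- spec$schema[[nm]]
      m <- spec$marginals[[nm]]
      cols[[nm]] <- if (d$kind == "categorical") {
        sample(names(m), n, replace = TRUE, prob = m)
      } else {
        sample(c(0L, 1L), n, replace = TRUE, prob = c(1 - m, m))
      }
    }
    do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  })
}

#' Simulate outcomes from a configurable true risk model
#'
#' The true 1-year risk is generated on the complementary log-log scale as
#' \deqn{risk_i = 1 - \exp(-\exp(\log(-\log S) + \delta_0 +
#'   \delta_1 \lambda \cdot lp_i^*))}
#' where `lp*` uses `coefficient_overrides` in place of the true model's own
#' values where supplied. `delta0` shifts the baseline (cloglog scale),
#' `delta1` distorts the slope, and overrides alter individual predictor
#' effects — the three axes along which external validation can break
#' (outcome incidence, overall effect strength, individual predictor
#' effects). The per-individual true risks are returned out-of-band so tests
#' can compute oracle quantities without polluting the cohort format.
#'
#' @param cohort Predictor table conforming to `true_model$schema`.
#' @param true_model An `oxrecal_coefs` acting as the generating model.
#' @param baseline_shift delta0, added on the cloglog scale. Default 0.
#' @param slope_factor delta1 (> 0), multiplies the linear predictor. Default 1.
#' @param coefficient_overrides Named list, predictor -> replacement
#'   coefficients (same shapes as in [coefficient_set()]).
#' @param seed Integer seed for the Bernoulli draws.
#' @return List with `cohort` (outcome and outcome_available columns added)
#'   and `true_risk` (numeric vector).
#' @export
simulate_outcomes <- function(cohort, true_model, baseline_shift = 0,
                              slope_factor = 1, coefficient_overrides = NULL,
                              seed = 1) {
  stopifnot(inherits(true_model, "oxrecal_coefs"))
  if (slope_factor <= 0) {
    oxrecal_error("slope_factor must be positive", "oxrecal_config_error")
  }
  gen <- true_model
  if (!is.null(coefficient_overrides)) {
    for (nm in names(coefficient_overrides)) {
      gen$coefficients[[nm]] <- coefficient_overrides[[nm]]
    }
    gen$coefficients <- validate_coefficients(gen$coefficients, gen$schema)
  }
  lp <- linear_predictor(cohort, gen)
  eta <- cloglog(1 - gen$baseline_survival) + baseline_shift +
    slope_factor * gen$recalibration_shape * lp
  risk <- inv_cloglog(eta)
  bad <- !is.finite(risk) | risk <= 0 | risk >= 1
  if (any(bad)) {
    oxrecal_error(sprintf("true risk outside (0,1) for record '%s'",
                          cohort$id[which(bad)[1]]),
                  "oxrecal_domain_error")
  }
  cohort$outcome <- withr::with_seed(seed,
    stats::rbinom(nrow(cohort), 1L, risk))
  cohort$outcome_available <- TRUE
  list(cohort = cohort, true_risk = risk)
}

#' Mark a random subset of outcomes as unavailable
#'
#' Emulates loss to follow-up: `round(rate * n)` individuals, chosen
#' uniformly with the given seed, have their outcome removed and
#' `outcome_available` set to `FALSE`. Downstream validation is
#' complete-case.
#'
#' @param cohort Cohort with an outcome column.
#' @param rate Missingness rate in \[0, 1).
#' @param seed Integer seed.
#' @return The cohort with missingness applied.
#' @export
apply_outcome_missingness <- function(cohort, rate, seed = 1) {
  if (rate < 0 || rate >= 1) {
    oxrecal_error("rate must lie in [0, 1)", "oxrecal_config_error")
  }
  if (rate == 0) return(cohort)
  n <- nrow(cohort)
  k <- round(rate * n)
  drop <- withr::with_seed(seed, sample.int(n, k))
  cohort$outcome[drop] <- NA_integer_
  if (!"outcome_available" %in% names(cohort)) {
    cohort$outcome_available <- TRUE
  }
  cohort$outcome_available[drop] <- FALSE
  cohort
}

#' Check the 100-events rule of thumb
#'
#' External validation of a prognostic model is conventionally powered by
#' requiring at least 100 events and 100 non-events; warns when the cohort
#' falls short.
#'
#' @param cohort Cohort with complete-case outcomes.
#' @return Invisibly, `min(events, nonevents)`; warns if below 100.
#' @export
check_events_rule <- function(cohort) {
  cc <- complete_cases(cohort)
  ev <- sum(cc$outcome)
  m <- min(ev, nrow(cc) - ev)
  if (m < 100) {
    warning(sprintf(paste0("validation cohort has only %d events and %d ",
                           "non-events; fewer than the 100 events/non-events ",
                           "rule of thumb"),
                    ev, nrow(cc) - ev), call. = FALSE)
  }
  invisible(m)
}

#' A deterministic worked example
#'
#' A 12-record cohort covering every incarceration band together with a
#' small coefficient set whose linear predictors are hand-computable (round
#' coefficient values for three predictors, all others absent from beta, the
#' two standard mean-imputation terms, S = 0.8). Used for regression tests
#' of the scoring path and shipped under `inst/extdata` together with its
#' expected scored output.
#'
#' @return List with `cohort` (including deterministic outcomes) and
#'   `coefs`.
#' @export
make_worked_fixture <- function() {
  schema <- oxrec_schema()
  coefs <- coefficient_set(
    schema = schema,
    baseline_survival = 0.8,
    coefficients = list(
      length_of_incarceration = c(m6_12 = 0.1, m12_24 = 0.2, ge24m = 0.3),
      violent_index_offense = 0.5,
      alcohol_misuse = 0.25
    ),
    imputed_terms = list(
      immigrant_status = list(beta = -0.0348, mean = 0.3075),
      neighborhood_deprivation = list(beta = 0.0259, mean = 0.39)
    ),
    label = "worked-example"
  )
  bands <- c("lt6m", "m6_12", "m12_24", "ge24m")
  cohort <- data.frame(
    id = sprintf("w%02d", 1:12),
    sex = rep(c("male", "male", "female"), 4),
    age_band = rep(c("a18_29", "a30_39", "a40_49", "a50plus"), 3),
    length_of_incarceration = rep(bands, each = 3),
    violent_index_offense = rep(c(0L, 1L), 6),
    previous_violent_crime = rep(c(0L, 0L, 1L), 4),
    civil_status = rep(c("other", "unmarried"), 6),
    education = rep(c("lt9y", "y9_11", "ge12y"), 4),
    employment = rep(c(1L, 0L), 6),
    income = rep(c("low", "stable"), 6),
    alcohol_misuse = rep(c(0L, 1L, 0L), 4),
    drug_misuse = rep(c(0L, 0L, 0L, 1L), 3),
    any_mental_disorder = rep(c(1L, 0L), 6),
    any_severe_mental_disorder = rep(c(0L, 0L, 0L, 1L), 3),
    outcome = rep(c(0L, 1L, 0L, 1L), 3),
    outcome_available = TRUE,
    stringsAsFactors = FALSE
  )
  list(cohort = validate_cohort(cohort, schema), coefs = coefs)
}
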