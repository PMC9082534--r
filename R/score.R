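#' Constant mean-imputation offset
#'
#' Predictors unavailable in the validation setting are "averaged out": every
#' individual receives the derivation-sample mean value, so the linear
#' predictor gains the constant \eqn{\sum_j \beta_j m_j}. With the published
#' terms for immigrant status (beta = -0.0348, mean = 0.3075) and
#' neighborhood deprivation (beta = 0.0259, mean = 0.39) this offset is
#' -0.0006.
#'
#' @param coefs An `oxrecal_coefs`.
#' @return A single number; 0 when there are no imputed terms.
#' @export
imputed_offset <- function(coefs) {
  stopifnot(inherits(coefs, "oxrecal_coefs"))
  if (length(coefs$imputed_terms) == 0L) return(0)
  sum(vapply(coefs$imputed_terms,
             function(t) t$beta * t$mean, numeric(1)))
}

#' Linear predictor for each cohort record
#'
#' Computes \eqn{LP_i = \sum \beta \cdot RF_i} over the collected predictors
#' plus the constant [imputed_offset()]. Reference levels contribute 0.
#' The recalibration shape `lambda` is *not* applied here; it belongs to
#' [predict_risk()].
#'
#' The result is quantized at 1e-9 so that covariate patterns whose
#' coefficient sums are mathematically equal score bitwise-identically
#' regardless of floating-point summation order; the quantum is far below
#' any meaningful coefficient difference and far above double-precision
#' summation error. This keeps tied risks exactly tied, so rank-based
#' statistics are invariant under baseline/slope recalibration.
#'
#' @param cohort Cohort data frame conforming to `coefs$schema`.
#' @param coefs An `oxrecal_coefs`.
#' @return Numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(cohort, coefs) {
  stopifnot(inherits(coefs, "oxrecal_coefs"))
  cohort <- validate_cohort(cohort, coefs$schema)
  lp <- rep(imputed_offset(coefs), nrow(cohort))
  for (nm in names(coefs$coefficients)) {
    d <- coefs$schema[[nm]]
    if (!nm %in% names(cohort)) {
      oxrecal_error(sprintf("cohort lacks predictor column '%s'", nm),
                    "oxrecal_cohort_error")
    }
    v <- cohort[[nm]]
    b <- coefs$coefficients[[nm]]
    if (d$kind == "categorical") {
      contrib <- rep(0, nrow(cohort))
      hit <- v %in% names(b)
      contrib[hit] <- b[v[hit]]
      lp <- lp + contrib
    } else {
      lp <- lp + b * as.numeric(v)
    }
  }
  round(lp, 9)  # stabilize mathematical ties (see Details)
}

#' Predicted risk from a linear predictor
#'
#' \deqn{risk = 1 - S^{\exp(\lambda \cdot LP)}}
#' Strictly increasing in `lp`; lies in (0, 1) for finite `lp`. On the
#' complementary log-log scale this is exactly linear:
#' `cloglog(risk) = log(-log S) + lambda * lp`, which is the algebraic bridge
#' the model-updating ladder fits on.
#'
#' @param lp Numeric vector of linear predictors (finite).
#' @param coefs An `oxrecal_coefs` supplying `S` and `lambda`.
#' @return Numeric vector of probabilities.
#' @export
predict_risk <- function(lp, coefs) {
  stopifnot(inherits(coefs, "oxrecal_coefs"))
  if (!all(is.finite(lp))) {
    oxrecal_error("linear predictor must be finite", "oxrecal_domain_error")
  }
  S <- coefs$baseline_survival
  lam <- coefs$recalibration_shape
  1 - S^exp(lam * lp)
}

#' Score a cohort
#'
#' Applies [linear_predictor()] and [predict_risk()] to every record,
#' preserving row order.
#'
#' @inheritParams linear_predictor
#' @return A data frame with columns `id`, `lp`, `risk`.
#' @export
score_cohort <- function(cohort, coefs) {
  cohort <- validate_cohort(cohort, coefs$schema)
  lp <- linear_predictor(cohort, coefs)
  data.frame(id = cohort$id, lp = lp, risk = predict_risk(lp, coefs),
             stringsAsFactors = FALSE)
}

#' Read a cohort CSV
#'
#' Expected layout: header row with `id`, one column per predictor (level
#' tokens as strings, binary predictors as 0/1), `outcome` (0/1/empty) and
#' optionally `outcome_available`; UTF-8, comma-separated. A missing
#' `outcome_available` column is inferred from empty outcomes.
#'
#' @param path CSV path.
#' @param schema Schema to validate against, default [oxrec_schema()].
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, schema = oxrec_schema()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  for (d in schema) {
    if (d$name %in% names(raw) && d$kind %in% c("binary", "continuous")) {
      raw[[d$name]] <- as.numeric(raw[[d$name]])
    }
  }
  if ("outcome" %in% names(raw)) raw$outcome <- as.integer(raw$outcome)
  if ("outcome_available" %in% names(raw)) {
    raw$outcome_available <- as.logical(raw$outcome_available)
  }
  validate_cohort(raw, schema)
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
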