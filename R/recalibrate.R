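#' Fit a complementary log-log recalibration
#'
#' Because the risk model `risk = 1 - S^exp(lambda * lp)` is exactly linear on
#' the complementary log-log scale, `cloglog(risk) = log(-log S) + lambda * lp`,
#' recalibration is fitted as a maximum-likelihood binary regression of the
#' outcome on the linear predictor with a cloglog link. The fitted intercept
#' `a` maps back to a baseline survival `S' = exp(-exp(a))` and the slope `b`
#' is the multiplicative recalibration value `lambda'`; this guarantees the
#' updated model round-trips into the same closed form.
#'
#' @param lp Linear predictors (without any recalibration shape applied).
#' @param outcomes Binary outcomes, both classes present.
#' @param free `"intercept"` fits only `a` with the slope pinned at `lambda`;
#'   `"intercept+slope"` frees both.
#' @param lambda Current recalibration shape, used as the pinned slope for the
#'   intercept-only fit. Default 1.
#' @return List with `a`, `b`, `baseline_survival` (= `exp(-exp(a))`),
#'   `fitted` probabilities and the iteration count.
#' @export
fit_cloglog_recalibration <- function(lp, outcomes,
                                      free = c("intercept", "intercept+slope"),
                                      lambda = 1) {
  free <- match.arg(free)
  check_metric_input(lp, outcomes, need_both_classes = TRUE)
  if (!all(is.finite(lp))) {
    oxrecal_error("linear predictor must be finite", "oxrecal_domain_error")
  }
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  if (free == "intercept") {
    fit <- stats::glm(outcomes ~ 1, offset = lambda * lp,
                      family = stats::binomial(link = "cloglog"), control = ctrl)
    a <- unname(stats::coef(fit)[1])
    b <- lambda
  } else {
    if (stats::var(lp) == 0) {
      oxrecal_error("slope unidentifiable: linear predictor is constant",
                    "oxrecal_fit_error")
    }
    fit <- stats::glm(outcomes ~ lp,
                      family = stats::binomial(link = "cloglog"), control = ctrl)
    a <- unname(stats::coef(fit)[1])
    b <- unname(stats::coef(fit)[2])
  }
  check_glm_health(fit)
  list(a = a, b = b, baseline_survival = exp(-exp(a)),
       fitted = unname(stats::fitted(fit)), iterations = fit$iter, fit = fit)
}

check_glm_health <- function(fit) {
  if (!fit$converged) {
    oxrecal_error(sprintf("cloglog fit did not converge in %d IRLS iterations",
                          fit$iter), "oxrecal_fit_error")
  }
  if (any(abs(stats::coef(fit)) > 20)) {
    oxrecal_error("cloglog fit appears separated (|coefficient| > 20)",
                  "oxrecal_fit_error")
  }
  invisible(TRUE)
}

new_recalibration <- function(stage, baseline_survival, shape,
                              reestimated = NULL, predictor = NULL) {
  structure(list(stage = stage,
                 baseline_survival = baseline_survival,
                 shape = shape,
                 reestimated = reestimated,
                 predictor = predictor),
            class = "oxrecal_recalibration")
}

#' @export
print.oxrecal_recalibration <- function(x, ...) {
  cat(sprintf("<oxrecal_recalibration stage '%s'>\n", x$stage))
  cat(sprintf("  S' = %.4f, lambda' = %.4f\n", x$baseline_survival, x$shape))
  if (!is.null(x$reestimated)) {
    cat(sprintf("  re-estimated %s: %s\n", x$predictor,
                paste(sprintf("%s=%.4f", names(x$reestimated), x$reestimated),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Apply recalibration parameters to a coefficient set
#'
#' Produces the updated coefficient set in the same `1 - S^exp(lambda * lp)`
#' form: the new baseline survival replaces `S`, the multiplicative value
#' replaces `lambda`, and any re-estimated dummies replace that predictor's
#' coefficients *inside* the lambda-multiplied bracket (they are stored as
#' fitted-dummy / lambda', so that `lambda' * lp` reproduces the fit exactly).
#'
#' @param coefs Original `oxrecal_coefs`.
#' @param params An `oxrecal_recalibration`.
#' @return The updated `oxrecal_coefs`.
#' @export
apply_recalibration <- function(coefs, params) {
  stopifnot(inherits(coefs, "oxrecal_coefs"),
            inherits(params, "oxrecal_recalibration"))
  coefficients <- coefs$coefficients
  if (!is.null(params$reestimated)) {
    coefficients[[params$predictor]] <- params$reestimated
  }
  coefficient_set(
    schema = coefs$schema,
    baseline_survival = params$baseline_survival,
    coefficients = coefficients,
    recalibration_shape = params$shape,
    imputed_terms = coefs$imputed_terms,
    label = sprintf("%s+%s", coefs$label, params$stage),
    horizon_years = coefs$horizon_years
  )
}

ladder_stage_names <- c("simple", "baseline", "slope", "selective")

prep_ladder_cohort <- function(cohort, coefs) {
  cohort <- complete_cases(validate_cohort(cohort, coefs$schema))
  if (nrow(cohort) == 0L) {
    oxrecal_error("no complete-case records to fit on", "oxrecal_cohort_error")
  }
  if (sum(cohort$outcome) == 0 || sum(cohort$outcome) == nrow(cohort)) {
    oxrecal_error("both outcome classes required for validation/updating",
                  "oxrecal_cohort_error")
  }
  cohort
}

#' Simple validation (no updating)
#'
#' Applies the original coefficients and reports performance unchanged.
#'
#' @param cohort Cohort with complete-case outcomes.
#' @param coefs Original `oxrecal_coefs`.
#' @param thresholds Risk cutoffs for the report.
#' @return List with `params` (echoing S and lambda, stage `"simple"`),
#'   `coefs` (unchanged) and `report` (an `oxrecal_report`).
#' @export
simple_validation <- function(cohort, coefs, thresholds = c(0.05, 0.10, 0.15, 0.20)) {
  cohort <- prep_ladder_cohort(cohort, coefs)
  scored <- score_cohort(cohort, coefs)
  params <- new_recalibration("simple", coefs$baseline_survival,
                              coefs$recalibration_shape)
  list(params = params, coefs = coefs,
       report = build_report(scored$risk, cohort$outcome, thresholds,
                             label = "simple"))
}

#' Update only the baseline risk
#'
#' Intercept-only cloglog refit with the (shape-scaled) linear predictor as a
#' fixed offset: only `S` moves, the rank order of predicted risks is
#' untouched.
#'
#' @inheritParams simple_validation
#' @return An `oxrecal_recalibration` with stage `"baseline"`.
#' @export
update_baseline_risk <- function(cohort, coefs) {
  cohort <- prep_ladder_cohort(cohort, coefs)
  lp <- linear_predictor(cohort, coefs)
  f <- fit_cloglog_recalibration(lp, cohort$outcome, free = "intercept",
                                 lambda = coefs$recalibration_shape)
  new_recalibration("baseline", f$baseline_survival, coefs$recalibration_shape)
}

#' Baseline risk plus a single multiplicative recalibration value
#'
#' Intercept-and-slope cloglog refit: the slope is the single multiplicative
#' value applied to the whole linear predictor (including the imputed
#' constant offset). A monotone transform of the risks, so discrimination is
#' unchanged.
#'
#' @inheritParams simple_validation
#' @return An `oxrecal_recalibration` with stage `"slope"`.
#' @export
fit_multiplicative_value <- function(cohort, coefs) {
  cohort <- prep_ladder_cohort(cohort, coefs)
  lp <- linear_predictor(cohort, coefs)
  f <- fit_cloglog_recalibration(lp, cohort$outcome, free = "intercept+slope")
  new_recalibration("slope", f$baseline_survival, f$b)
}

#' Selective re-estimation of one predictor
#'
#' Refits the chosen categorical predictor's non-reference dummy coefficients
#' freely, together with a free intercept and a free slope on the partial
#' linear predictor (everything except the chosen predictor). Used when one
#' predictor's effect genuinely differs between derivation and validation
#' populations; unlike the earlier stages this can change the rank order of
#' predicted risks. The refitted dummies are stored inside the
#' lambda'-multiplied bracket (i.e. divided by the fitted slope).
#'
#' @inheritParams simple_validation
#' @param predictor Name of a categorical schema predictor with coefficients.
#' @return An `oxrecal_recalibration` with stage `"selective"`.
#' @export
reestimate_predictor <- function(cohort, coefs,
                                 predictor = "length_of_incarceration") {
  cohort <- prep_ladder_cohort(cohort, coefs)
  d <- coefs$schema[[predictor]]
  if (is.null(d) || d$kind != "categorical") {
    oxrecal_error(sprintf("'%s' must be a categorical schema predictor", predictor),
                  "oxrecal_fit_error")
  }
  counts <- table(factor(cohort[[predictor]], levels = d$levels))
  if (any(counts == 0)) {
    oxrecal_error(sprintf("no individuals at level(s) %s of '%s'",
                          paste(names(counts)[counts == 0], collapse = ", "),
                          predictor),
                  "oxrecal_fit_error")
  }
  # partial lp: drop the predictor's own contribution, keep everything else
  reduced <- coefs
  reduced$coefficients[[predictor]] <- NULL
  partial_lp <- linear_predictor(cohort, reduced)
  dummies <- stats::model.matrix(
    ~ f, data.frame(f = factor(cohort[[predictor]], levels = d$levels)))[, -1, drop = FALSE]
  colnames(dummies) <- d$levels[-1]
  if (stats::var(partial_lp) == 0) {
    oxrecal_error("slope unidentifiable: partial linear predictor is constant",
                  "oxrecal_fit_error")
  }
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  dat <- data.frame(y = cohort$outcome, partial_lp = partial_lp, dummies,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(
    "y ~ partial_lp +", paste(sprintf("`%s`", d$levels[-1]), collapse = " + ")))
  fit <- stats::glm(fml, data = dat,
                    family = stats::binomial(link = "cloglog"), control = ctrl)
  check_glm_health(fit)
  cf <- stats::coef(fit)
  a <- unname(cf[1])
  b <- unname(cf[2])
  gam <- unname(cf[-(1:2)])  # formula preserves the dummy order
  names(gam) <- d$levels[-1]
  params <- new_recalibration("selective", exp(-exp(a)), b,
                              reestimated = gam / b, predictor = predictor)
  params$fit <- fit
  params
}

#' Run the incremental model-updating ladder
#'
#' Executes the requested stages in the fixed order
#' simple -> baseline -> slope -> selective, fitting each on the same
#' (complete-case) cohort and re-reporting performance after each stage.
#' Because the stages are nested on the cloglog scale, in-sample
#' log-likelihood is non-decreasing down the ladder.
#'
#' @inheritParams simple_validation
#' @param stages Ordered subset of `c("simple", "baseline", "slope",
#'   "selective")`.
#' @param predictor Predictor for the selective stage.
#' @return An `oxrecal_ladder`: per-stage list of `params`, `coefs`, `report`
#'   and `loglik`, plus `final_coefs`.
#' @export
run_ladder <- function(cohort, coefs,
                       stages = c("simple", "baseline", "slope", "selective"),
                       thresholds = c(0.05, 0.10, 0.15, 0.20),
                       predictor = "length_of_incarceration") {
  stages <- as.character(stages)
  if (!all(stages %in% ladder_stage_names)) {
    oxrecal_error(sprintf("unknown stage(s): %s",
                          paste(setdiff(stages, ladder_stage_names), collapse = ", ")),
                  "oxrecal_config_error")
  }
  if (is.unsorted(match(stages, ladder_stage_names), strictly = TRUE)) {
    oxrecal_error("stages must respect the order simple -> baseline -> slope -> selective",
                  "oxrecal_config_error")
  }
  cohort <- prep_ladder_cohort(cohort, coefs)
  out <- list()
  final <- coefs
  for (st in stages) {
    res <- switch(st,
      simple = {
        sv <- simple_validation(cohort, coefs, thresholds)
        list(params = sv$params, coefs = sv$coefs, report = sv$report)
      },
      baseline = {
        p <- update_baseline_risk(cohort, coefs)
        cf <- apply_recalibration(coefs, p)
        list(params = p, coefs = cf,
             report = build_report(score_cohort(cohort, cf)$risk, cohort$outcome,
                                   thresholds, label = st))
      },
      slope = {
        p <- fit_multiplicative_value(cohort, coefs)
        cf <- apply_recalibration(coefs, p)
        list(params = p, coefs = cf,
             report = build_report(score_cohort(cohort, cf)$risk, cohort$outcome,
                                   thresholds, label = st))
      },
      selective = {
        p <- reestimate_predictor(cohort, coefs, predictor)
        p$fit <- NULL
        cf <- apply_recalibration(coefs, p)
        list(params = p, coefs = cf,
             report = build_report(score_cohort(cohort, cf)$risk, cohort$outcome,
                                   thresholds, label = st))
      })
    risk <- score_cohort(cohort, res$coefs)$risk
    res$loglik <- sum(cohort$outcome * log(clip_prob(risk)) +
                      (1 - cohort$outcome) * log(clip_prob(1 - risk)))
    out[[st]] <- res
    final <- res$coefs
  }
  structure(list(stages = out, final_coefs = final), class = "oxrecal_ladder")
}

#' @export
print.oxrecal_ladder <- function(x, ...) {
  cat("<oxrecal_ladder>\n")
  cat(sprintf("  %-10s %8s %8s %7s %7s %7s %7s %7s\n",
              "stage", "S'", "lambda'", "AUC", "CITL", "slope", "Brier", "E:O"))
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    cat(sprintf("  %-10s %8.4f %8.4f %7.3f %+7.3f %7.3f %7.4f %7.3f\n",
                st, s$params$baseline_survival, s$params$shape,
                s$report$auc, s$report$citl, s$report$slope,
                s$report$brier, s$report$eo_ratio))
  }
  invisible(x)
}
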