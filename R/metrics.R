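#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 is best, 1 worst. For a perfectly calibrated predictor the
#' expected Brier score is `mean(risk * (1 - risk))`, and the constant
#' predictor at the prevalence scores `prev * (1 - prev)`.
#'
#' @param risks Predicted probabilities.
#' @param outcomes Binary outcomes (0/1), same length.
#' @return A single number in \[0, 1\].
#' @export
brier_score <- function(risks, outcomes) {
  check_metric_input(risks, outcomes, need_both_classes = FALSE)
  mean((risks - outcomes)^2)
}

check_metric_input <- function(risks, outcomes, need_both_classes = TRUE) {
  if (length(risks) == 0L) {
    oxrecal_error("empty input", "oxrecal_metric_error")
  }
  if (length(risks) != length(outcomes)) {
    oxrecal_error("risks and outcomes must have equal length", "oxrecal_metric_error")
  }
  if (anyNA(risks) || anyNA(outcomes)) {
    oxrecal_error("missing values in metric input", "oxrecal_metric_error")
  }
  if (!all(outcomes %in% c(0, 1))) {
    oxrecal_error("outcomes must be 0/1", "oxrecal_metric_error")
  }
  if (need_both_classes && (sum(outcomes) == 0 || sum(outcomes) == length(outcomes))) {
    oxrecal_error("both outcome classes must be present", "oxrecal_metric_error")
  }
  invisible(TRUE)
}

#' Area under the ROC curve (c index)
#'
#' Mann-Whitney concordance: over all event/non-event pairs, the fraction in
#' which the event individual scores higher, ties counting one half. Computed
#' from midranks, which is algebraically identical to trapezoidal integration
#' of the ROC curve.
#'
#' @param scores Risk scores (any monotone scale).
#' @param outcomes Binary outcomes with at least one event and one non-event.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, outcomes) {
  check_metric_input(scores, outcomes)
  if (sum(outcomes) == 0 || sum(outcomes) == length(outcomes)) {
    oxrecal_error("AUC undefined for single-class outcomes", "oxrecal_metric_error")
  }
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement components: for each event, the mean of
# psi(event_score, control_score) over all controls, and vice versa.
delong_components <- function(scores, outcomes) {
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  m <- length(x); n <- length(y)
  # midrank trick: placement values from joint and group-wise ranks
  rj <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (rj[seq_len(m)] - rx) / n
  v01 <- 1 - (rj[m + seq_len(n)] - ry) / m
  list(theta = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Confidence interval for the AUC
#'
#' Default is the DeLong variance with a normal interval, truncated to
#' \[0, 1\]; degenerate variance (e.g. perfect separation) collapses the
#' interval onto the point estimate. A seeded non-parametric bootstrap
#' percentile interval is available as an alternative.
#'
#' @inheritParams auc
#' @param level Confidence level, default 0.95.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (bootstrap method only).
#' @param seed Integer seed for the bootstrap.
#' @return Named vector `c(auc, lower, upper)`.
#' @export
auc_ci <- function(scores, outcomes, level = 0.95,
                   method = c("delong", "bootstrap"),
                   n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  point <- auc(scores, outcomes)
  if (method == "delong") {
    cmp <- delong_components(scores, outcomes)
    v <- stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
    se <- sqrt(max(v, 0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- max(0, point - z * se)
    hi <- min(1, point + z * se)
  } else {
    idx1 <- which(outcomes == 1)
    idx0 <- which(outcomes == 0)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- c(sample(idx1, replace = TRUE), sample(idx0, replace = TRUE))
        auc(scores[i], outcomes[i])
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    lo <- qs[1]; hi <- qs[2]
  }
  c(auc = point, lower = lo, upper = hi)
}

#' Calibration-in-the-large
#'
#' Intercept of a maximum-likelihood logistic regression of the outcome on
#' the fixed offset `logit(risk)` with the slope pinned at 1. Zero means the
#' average predicted risk agrees with the observed incidence; positive values
#' mean the model underestimates risk in the validation population.
#'
#' @inheritParams brier_score
#' @return CITL on the logit scale.
#' @export
calibration_intercept <- function(risks, outcomes) {
  check_metric_input(risks, outcomes)
  off <- stats::qlogis(clip_prob(risks))
  fit <- stats::glm(outcomes ~ 1, offset = off, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    oxrecal_error(sprintf("CITL fit did not converge in %d IRLS iterations",
                          fit$iter), "oxrecal_fit_error")
  }
  unname(stats::coef(fit)[1])
}

#' Calibration slope
#'
#' Slope of a maximum-likelihood logistic regression of the outcome on
#' `logit(risk)` with a free intercept. 1 means predictor effects carry the
#' right overall weight; values below 1 indicate overfitting (effects too
#' strong), above 1 underfitting.
#'
#' @inheritParams brier_score
#' @return The fitted slope.
#' @export
calibration_slope <- function(risks, outcomes) {
  check_metric_input(risks, outcomes)
  lg <- stats::qlogis(clip_prob(risks))
  if (stats::var(lg) == 0) {
    oxrecal_error("calibration slope unidentifiable: logit(risk) is constant",
                  "oxrecal_fit_error")
  }
  fit <- stats::glm(outcomes ~ lg, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    oxrecal_error(sprintf("slope fit did not converge in %d IRLS iterations",
                          fit$iter), "oxrecal_fit_error")
  }
  unname(stats::coef(fit)[2])
}

#' Expected-to-observed ratio
#'
#' Sum of predicted risks over the number of observed events; 1 is perfect
#' average calibration, values below 1 indicate underestimation of risk.
#'
#' @inheritParams brier_score
#' @return E:O ratio.
#' @export
eo_ratio <- function(risks, outcomes) {
  check_metric_input(risks, outcomes, need_both_classes = FALSE)
  if (sum(outcomes) == 0) {
    oxrecal_error("E:O undefined with zero observed events", "oxrecal_metric_error")
  }
  sum(risks) / sum(outcomes)
}

#' Quantile calibration bins
#'
#' Ranks individuals by predicted risk and cuts them into `n_bins` equal-size
#' quantile groups (deciles by default), with boundary ties resolved by
#' stable rank order. Per bin: size, mean predicted risk and observed event
#' proportion. The global CITL, slope and E:O are attached.
#'
#' @inheritParams brier_score
#' @param n_bins Number of quantile groups, default 10, minimum 2.
#' @return An `oxrecal_calibration`: a data frame `bin, n, mean_predicted,
#'   observed` with attributes `citl`, `slope`, `eo_ratio`.
#' @export
calibration_bins <- function(risks, outcomes, n_bins = 10) {
  check_metric_input(risks, outcomes, need_both_classes = FALSE)
  if (n_bins < 2) {
    oxrecal_error("n_bins must be at least 2", "oxrecal_metric_error")
  }
  n <- length(risks)
  if (n < n_bins) {
    oxrecal_error("need at least n_bins observations", "oxrecal_metric_error")
  }
  ord <- order(risks)  # stable: ties keep input order
  bin_sorted <- ceiling(seq_len(n) * n_bins / n)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  df <- data.frame(
    bin = seq_len(n_bins),
    n = as.vector(tapply(risks, bin, length)),
    mean_predicted = as.vector(tapply(risks, bin, mean)),
    observed = as.vector(tapply(outcomes, bin, mean))
  )
  attr(df, "citl") <- tryCatch(calibration_intercept(risks, outcomes),
                               error = function(e) NA_real_)
  attr(df, "slope") <- tryCatch(calibration_slope(risks, outcomes),
                                error = function(e) NA_real_)
  attr(df, "eo_ratio") <- tryCatch(eo_ratio(risks, outcomes),
                                   error = function(e) NA_real_)
  class(df) <- c("oxrecal_calibration", "data.frame")
  df
}

#' Classification metrics at a risk threshold
#'
#' Classifies predicted-positive when `risk >= threshold` (the boundary
#' counts as positive) and tabulates the 2x2 table with sensitivity,
#' specificity, PPV and NPV, each with a Wilson 95% interval. An empty
#' denominator (e.g. no predicted positives for PPV) yields `NA` estimates.
#'
#' @inheritParams brier_score
#' @param threshold Risk cutoff in (0, 1).
#' @param level Confidence level for the Wilson intervals.
#' @return One-row data frame with counts, proportions and interval bounds.
#' @export
threshold_metrics <- function(risks, outcomes, threshold, level = 0.95) {
  check_metric_input(risks, outcomes)
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1) {
    oxrecal_error("threshold must lie strictly in (0, 1)", "oxrecal_metric_error")
  }
  pos <- risks >= threshold
  tp <- sum(pos & outcomes == 1)
  fp <- sum(pos & outcomes == 0)
  fn <- sum(!pos & outcomes == 1)
  tn <- sum(!pos & outcomes == 0)
  se <- wilson_interval(tp, tp + fn, level)
  sp <- wilson_interval(tn, tn + fp, level)
  ppv <- wilson_interval(tp, tp + fp, level)
  npv <- wilson_interval(tn, tn + fn, level)
  data.frame(
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = se[["estimate"]], sens_lower = se[["lower"]], sens_upper = se[["upper"]],
    specificity = sp[["estimate"]], spec_lower = sp[["lower"]], spec_upper = sp[["upper"]],
    ppv = ppv[["estimate"]], ppv_lower = ppv[["lower"]], ppv_upper = ppv[["upper"]],
    npv = npv[["estimate"]], npv_lower = npv[["lower"]], npv_upper = npv[["upper"]]
  )
}

#' Assemble a validation report
#'
#' Bundles every performance measure of one validation stage: cohort size,
#' events and incidence; Brier score; AUC with confidence interval;
#' calibration (CITL, slope, E:O, quantile bins); and a threshold
#' classification table.
#'
#' @param risks Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param thresholds Ascending risk cutoffs, default `c(0.05, 0.10, 0.15, 0.20)`.
#' @param label Stage label carried in the report.
#' @param n_bins Calibration bins, default 10.
#' @param level Confidence level, default 0.95.
#' @param auc_method Passed to [auc_ci()].
#' @return An object of class `oxrecal_report`.
#' @export
build_report <- function(risks, outcomes, thresholds = c(0.05, 0.10, 0.15, 0.20),
                         label = "", n_bins = 10, level = 0.95,
                         auc_method = "delong") {
  check_metric_input(risks, outcomes)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    oxrecal_error("thresholds must be strictly ascending", "oxrecal_metric_error")
  }
  n <- length(outcomes)
  events <- sum(outcomes)
  aci <- auc_ci(risks, outcomes, level = level, method = auc_method)
  tab <- do.call(rbind, lapply(thresholds, function(t) {
    threshold_metrics(risks, outcomes, t, level)
  }))
  structure(list(
    label = label,
    n = n,
    events = events,
    incidence = events / n,
    brier = brier_score(risks, outcomes),
    auc = aci[["auc"]], auc_lower = aci[["lower"]], auc_upper = aci[["upper"]],
    citl = calibration_intercept(risks, outcomes),
    slope = calibration_slope(risks, outcomes),
    eo_ratio = eo_ratio(risks, outcomes),
    calibration = calibration_bins(risks, outcomes, n_bins),
    thresholds = tab
  ), class = "oxrecal_report")
}

#' @export
print.oxrecal_report <- function(x, ...) {
  cat(sprintf("<oxrecal_report%s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  cat(sprintf("  n = %d, events = %d (incidence %.1f%%)\n",
              x$n, x$events, 100 * x$incidence))
  cat(sprintf("  Brier %.4f | AUC %.3f (%.3f-%.3f)\n",
              x$brier, x$auc, x$auc_lower, x$auc_upper))
  cat(sprintf("  CITL %+.3f | slope %.3f | E:O %.3f\n",
              x$citl, x$slope, x$eo_ratio))
  cat(sprintf("  thresholds: %s\n",
              paste(sprintf("%g%%", 100 * x$thresholds$threshold), collapse = ", ")))
  invisible(x)
}
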