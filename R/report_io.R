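#' Serialize a validation report to JSON
#'
#' Full precision; presentation rounding happens only in the Markdown
#' rendering.
#'
#' @param report An `oxrecal_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "oxrecal_report"))
  cal <- report$calibration
  doc <- list(
    label = report$label,
    n = report$n, events = report$events, incidence = report$incidence,
    brier = report$brier,
    auc = list(estimate = report$auc, lower = report$auc_lower,
               upper = report$auc_upper),
    citl = report$citl, slope = report$slope, eo_ratio = report$eo_ratio,
    calibration_bins = as.data.frame(cal),
    thresholds = report$thresholds
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render a threshold table as Markdown
#'
#' Mirrors the conventional updated-model summary layout: one row per risk
#' threshold with sensitivity, specificity, PPV and NPV, percentages rounded
#' to the nearest whole percent with their 95% intervals.
#'
#' @param report An `oxrecal_report`.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "oxrecal_report"))
  pct <- function(x) ifelse(is.na(x), "--", sprintf("%.0f%%", 100 * x))
  cell <- function(est, lo, hi) {
    ifelse(is.na(est), "--",
           sprintf("%s (%s-%s)", pct(est), pct(lo), pct(hi)))
  }
  t <- report$thresholds
  c(sprintf("# Validation report%s",
            if (nzchar(report$label)) paste0(": ", report$label) else ""),
    "",
    sprintf("- n = %d, events = %d, incidence = %s",
            report$n, report$events, pct(report$incidence)),
    sprintf("- Brier score = %.4f", report$brier),
    sprintf("- AUC (c-index) = %.2f (95%% CI %.2f-%.2f)",
            report$auc, report$auc_lower, report$auc_upper),
    sprintf("- CITL = %.2f, calibration slope = %.2f, E:O = %.2f",
            report$citl, report$slope, report$eo_ratio),
    "",
    "| Risk threshold | Sensitivity | Specificity | PPV | NPV |",
    "|---|---|---|---|---|",
    sprintf("| **%.0f%%** | %s | %s | %s | %s |",
            100 * t$threshold,
            cell(t$sensitivity, t$sens_lower, t$sens_upper),
            cell(t$specificity, t$spec_lower, t$spec_upper),
            cell(t$ppv, t$ppv_lower, t$ppv_upper),
            cell(t$npv, t$npv_lower, t$npv_upper)))
}

#' Export calibration-plot data as TSV
#'
#' Columns `bin`, `mean_predicted`, `observed`, `n` — the data behind a
#' predicted-vs-observed calibration plot.
#'
#' @param bins An `oxrecal_calibration` (or a report, whose bins are used).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_tsv <- function(bins, path) {
  if (inherits(bins, "oxrecal_report")) bins <- bins$calibration
  stopifnot(inherits(bins, "oxrecal_calibration"))
  utils::write.table(bins[, c("bin", "mean_predicted", "observed", "n")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calibration plot
#'
#' Mean predicted risk against observed event proportion per quantile bin,
#' with the identity diagonal. Points below the diagonal indicate
#' underestimation of risk.
#'
#' @param x An `oxrecal_calibration`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.oxrecal_calibration <- function(x, ...) {
  lim <- c(0, max(x$mean_predicted, x$observed) * 1.05)
  graphics::plot(x$mean_predicted, x$observed, xlim = lim, ylim = lim,
                 xlab = "Mean predicted risk", ylab = "Observed proportion",
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
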