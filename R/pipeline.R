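# File-level pipeline commands: simulate -> score -> validate -> update.
# Each validates its inputs fully before writing any output file, and is
# deterministic given its seed, so re-runs overwrite identically.

resolve_coefs <- function(coefs_file) {
  if (!file.exists(coefs_file)) {
    oxrecal_error(sprintf("coefficient file '%s' does not exist", coefs_file),
                  "oxrecal_config_error")
  }
  read_coefficient_set(coefs_file)
}

#' Simulate a cohort to files
#'
#' Samples a synthetic predictor table, draws outcomes from the chosen true
#' model with optional distortions, applies outcome missingness, and writes
#' the cohort CSV plus a truth JSON (per-individual true risks and the
#' generating parameters). Warns when the generated complete-case cohort
#' falls below the 100 events/non-events rule of thumb.
#'
#' @param out_cohort,out_truth Output paths (CSV, JSON).
#' @param n Cohort size.
#' @param preset `"tajik"` or `"sweden-approx"` marginal preset.
#' @param marginals Explicit marginals, overriding `preset`.
#' @param true_model An `oxrecal_coefs`; default the bundled
#'   `"sweden-synthetic"` set.
#' @param baseline_shift,slope_factor,coefficient_overrides Distortions, see
#'   [simulate_outcomes()].
#' @param missing_rate Outcome missingness rate, default 0.
#' @param seed Integer seed driving all draws.
#' @return Invisibly, a list with the cohort and true risks.
#' @export
run_simulate <- function(out_cohort, out_truth, n, preset = c("tajik", "sweden-approx"),
                         marginals = NULL, true_model = NULL,
                         baseline_shift = 0, slope_factor = 1,
                         coefficient_overrides = NULL,
                         missing_rate = 0, seed = 1) {
  preset <- match.arg(preset)
  if (is.null(marginals)) {
    marginals <- if (preset == "tajik") tajik_marginals() else sweden_marginals()
  }
  if (is.null(true_model)) true_model <- oxrec_coefs("sweden-synthetic")
  spec <- cohort_spec(n, marginals, seed = seed, schema = true_model$schema)
  cohort <- sample_cohort(spec)
  sim <- simulate_outcomes(cohort, true_model,
                           baseline_shift = baseline_shift,
                           slope_factor = slope_factor,
                           coefficient_overrides = coefficient_overrides,
                           seed = seed + 1L)
  out <- sim$cohort
  if (missing_rate > 0) {
    out <- apply_outcome_missingness(out, missing_rate, seed = seed + 2L)
  }
  check_events_rule(out)
  write_cohort(out, out_cohort)
  jsonlite::write_json(
    list(seed = seed, n = n, preset = preset,
         true_model = true_model$label,
         baseline_shift = baseline_shift, slope_factor = slope_factor,
         coefficient_overrides = coefficient_overrides,
         missing_rate = missing_rate,
         true_risk = sim$true_risk),
    out_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = out, true_risk = sim$true_risk))
}

#' Score a cohort file
#'
#' @param cohort_file Cohort CSV.
#' @param coefs_file Coefficient-set JSON.
#' @param out_file Scored CSV (`id, lp, risk`).
#' @return Invisibly, the scored data frame.
#' @export
run_score <- function(cohort_file, coefs_file, out_file) {
  coefs <- resolve_coefs(coefs_file)
  cohort <- read_cohort(cohort_file, coefs$schema)
  scored <- score_cohort(cohort, coefs)
  message(sprintf("scored %d records with '%s' (imputed offset %.6f)",
                  nrow(scored), coefs$label, imputed_offset(coefs)))
  utils::write.csv(format_scored(scored), out_file, row.names = FALSE,
                   quote = FALSE)
  invisible(scored)
}

format_scored <- function(scored) {
  data.frame(id = scored$id,
             lp = sprintf("%.10g", scored$lp),
             risk = sprintf("%.10g", scored$risk),
             stringsAsFactors = FALSE)
}

#' Validate a scored cohort and write report files
#'
#' Writes `report.json` (full precision), `report.md` (threshold table with
#' whole-percent rounding) and `calibration.tsv` under `out_dir`.
#'
#' @inheritParams run_score
#' @param out_dir Output directory, created if needed.
#' @param thresholds Risk cutoffs, default `c(0.05, 0.10, 0.15, 0.20)`.
#' @param label Report label.
#' @return Invisibly, the `oxrecal_report`.
#' @export
run_validate <- function(cohort_file, coefs_file, out_dir,
                         thresholds = c(0.05, 0.10, 0.15, 0.20),
                         label = "validation") {
  coefs <- resolve_coefs(coefs_file)
  cohort <- complete_cases(read_cohort(cohort_file, coefs$schema))
  if (nrow(cohort) == 0L || length(unique(cohort$outcome)) < 2L) {
    oxrecal_error("validation needs complete-case outcomes of both classes",
                  "oxrecal_cohort_error")
  }
  scored <- score_cohort(cohort, coefs)
  report <- build_report(scored$risk, cohort$outcome, thresholds, label = label)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report_json(report, file.path(out_dir, "report.json"))
  writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  write_calibration_tsv(report, file.path(out_dir, "calibration.tsv"))
  invisible(report)
}

#' Run the updating ladder and write its artifacts
#'
#' Writes one `report_<stage>.json` per executed stage, the final
#' recalibrated coefficient set as `coefs_final.json` (same dialect as
#' [write_coefficient_set()]), and a stage-comparison Markdown table
#' `stages.md`.
#'
#' @inheritParams run_validate
#' @param stages Ordered subset of the ladder stages.
#' @param predictor Predictor for the selective stage.
#' @return Invisibly, the `oxrecal_ladder`.
#' @export
run_update <- function(cohort_file, coefs_file, out_dir,
                       stages = c("simple", "baseline", "slope", "selective"),
                       thresholds = c(0.05, 0.10, 0.15, 0.20),
                       predictor = "length_of_incarceration") {
  coefs <- resolve_coefs(coefs_file)
  cohort <- read_cohort(cohort_file, coefs$schema)
  ladder <- run_ladder(cohort, coefs, stages = stages, thresholds = thresholds,
                       predictor = predictor)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(ladder$stages)) {
    write_report_json(ladder$stages[[st]]$report,
                      file.path(out_dir, sprintf("report_%s.json", st)))
  }
  write_coefficient_set(ladder$final_coefs, file.path(out_dir, "coefs_final.json"))
  writeLines(ladder_markdown(ladder), file.path(out_dir, "stages.md"))
  invisible(ladder)
}

ladder_markdown <- function(ladder) {
  stopifnot(inherits(ladder, "oxrecal_ladder"))
  rows <- vapply(names(ladder$stages), function(st) {
    s <- ladder$stages[[st]]
    sprintf("| %s | %.4f | %.4f | %.3f | %.3f | %.3f | %.4f | %.3f |",
            st, s$params$baseline_survival, s$params$shape,
            s$report$auc, s$report$citl, s$report$slope,
            s$report$brier, s$report$eo_ratio)
  }, character(1))
  c("| Stage | S' | lambda' | AUC | CITL | Slope | Brier | E:O |",
    "|---|---|---|---|---|---|---|---|",
    rows)
}
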