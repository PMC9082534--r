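#' Define a single predictor
#'
#' A predictor definition is the unit of a [predictor_schema()]: its name,
#' measurement kind, declared levels (categorical only, first level is the
#' reference) and whether the validation cohort is required to supply it.
#' Predictors with `required = FALSE` are those absent from the validation
#' setting and carried in a coefficient set's mean-imputation terms instead.
#'
#' @param name Predictor name (unique token).
#' @param kind One of `"binary"`, `"categorical"`, `"continuous"`.
#' @param levels Ordered character vector of level names for categorical
#'   predictors; the first level is the reference and carries an implicit
#'   coefficient of 0.
#' @param required Logical; must the cohort table contain this column?
#' @return An object of class `oxrecal_predictor`.
#' @export
predictor_def <- function(name, kind = c("binary", "categorical", "continuous"),
                          levels = NULL, required = TRUE) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    oxrecal_error("predictor name must be a non-empty string", "oxrecal_schema_error")
  }
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2L || anyDuplicated(levels)) {
      oxrecal_error(
        sprintf("categorical predictor '%s' needs >= 2 distinct levels", name),
        "oxrecal_schema_error")
    }
  } else if (!is.null(levels)) {
    oxrecal_error(
      sprintf("levels are only meaningful for categorical predictors ('%s')", name),
      "oxrecal_schema_error")
  }
  structure(list(name = name, kind = kind, levels = levels,
                 required = isTRUE(required)),
            class = "oxrecal_predictor")
}

#' Assemble a predictor schema
#'
#' @param ... [predictor_def()] objects, in the order the linear predictor
#'   enumerates them.
#' @return An object of class `oxrecal_schema` (a named list of definitions).
#' @export
predictor_schema <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.list(defs[[1]]) &&
      !inherits(defs[[1]], "oxrecal_predictor")) {
    defs <- defs[[1]]
  }
  ok <- vapply(defs, inherits, logical(1), "oxrecal_predictor")
  if (!all(ok)) {
    oxrecal_error("all schema entries must be predictor_def() objects",
                  "oxrecal_schema_error")
  }
  nms <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    oxrecal_error(sprintf("duplicate predictor name(s): %s",
                          paste(unique(nms[duplicated(nms)]), collapse = ", ")),
                  "oxrecal_schema_error")
  }
  names(defs) <- nms
  structure(defs, class = "oxrecal_schema")
}

#' The default OxRec predictor schema
#'
#' Enumerates the routinely collected predictors of the OxRec violent
#' reoffending model across its three domains — criminal history (length of
#' incarceration in four bands, violent index offense, previous violent
#' crime), sociodemographic (sex, age band, civil status, education,
#' employment, income) and clinical (alcohol misuse, drug misuse, any mental
#' disorder, any severe mental disorder) — plus the two predictors typically
#' unavailable outside the derivation registries (immigrant status,
#' neighborhood deprivation), flagged imputable so coefficient sets can carry
#' them as mean-imputation offsets.
#'
#' Age is banded by default; a coefficient set using continuous age can
#' supply its own schema.
#'
#' @return An `oxrecal_schema`.
#' @export
oxrec_schema <- function() {
  predictor_schema(
    predictor_def("sex", "categorical", c("male", "female")),
    predictor_def("age_band", "categorical", c("a18_29", "a30_39", "a40_49", "a50plus")),
    predictor_def("length_of_incarceration", "categorical",
                  c("lt6m", "m6_12", "m12_24", "ge24m")),
    predictor_def("violent_index_offense", "binary"),
    predictor_def("previous_violent_crime", "binary"),
    predictor_def("civil_status", "categorical", c("other", "unmarried")),
    predictor_def("education", "categorical", c("lt9y", "y9_11", "ge12y")),
    predictor_def("employment", "binary"),
    predictor_def("income", "categorical", c("low", "stable")),
    predictor_def("alcohol_misuse", "binary"),
    predictor_def("drug_misuse", "binary"),
    predictor_def("any_mental_disorder", "binary"),
    predictor_def("any_severe_mental_disorder", "binary"),
    predictor_def("immigrant_status", "binary", required = FALSE),
    predictor_def("neighborhood_deprivation", "continuous", required = FALSE)
  )
}

#' @export
print.oxrecal_schema <- function(x, ...) {
  cat(sprintf("<oxrecal_schema: %d predictors>\n", length(x)))
  for (d in x) {
    lv <- if (d$kind == "categorical") {
      sprintf(" [%s]", paste(d$levels, collapse = ", "))
    } else ""
    cat(sprintf("  %-28s %-11s%s%s\n", d$name, d$kind, lv,
                if (d$required) "" else " (imputable)"))
  }
  invisible(x)
}

schema_names <- function(schema) names(schema)

required_predictors <- function(schema) {
  names(schema)[vapply(schema, `[[`, logical(1), "required")]
}

#' Validate a cohort table against a schema
#'
#' Checks that every required predictor column is present, that categorical
#' values lie in the declared levels, that binary values are 0/1, and that
#' `outcome` (if present) is 0/1/NA. Adds an `outcome_available` column,
#' inferred from non-missing `outcome`, when absent.
#'
#' @param cohort A data frame with one row per released individual: an `id`
#'   column, one column per required predictor, and optionally `outcome` and
#'   `outcome_available`.
#' @param schema An `oxrecal_schema`, default [oxrec_schema()].
#' @return The validated cohort data frame (invisibly augmented with
#'   `outcome_available` if it was missing).
#' @export
validate_cohort <- function(cohort, schema = oxrec_schema()) {
  if (!is.data.frame(cohort)) {
    oxrecal_error("cohort must be a data frame", "oxrecal_cohort_error")
  }
  if (!"id" %in% names(cohort)) {
    oxrecal_error("cohort is missing the 'id' column", "oxrecal_cohort_error")
  }
  if (anyDuplicated(cohort$id)) {
    oxrecal_error("cohort ids must be unique", "oxrecal_cohort_error")
  }
  for (nm in required_predictors(schema)) {
    if (!nm %in% names(cohort)) {
      oxrecal_error(sprintf("cohort is missing required predictor column '%s'", nm),
                    "oxrecal_cohort_error")
    }
  }
  for (d in schema) {
    if (!d$name %in% names(cohort)) next
    v <- cohort[[d$name]]
    if (d$kind == "categorical") {
      bad <- !is.na(v) & !(v %in% d$levels)
      if (any(bad)) {
        oxrecal_error(
          sprintf("record '%s': value '%s' is not a declared level of '%s'",
                  cohort$id[which(bad)[1]], v[which(bad)[1]], d$name),
          "oxrecal_cohort_error")
      }
    } else if (d$kind == "binary") {
      bad <- !is.na(v) & !(v %in% c(0, 1))
      if (any(bad)) {
        oxrecal_error(
          sprintf("record '%s': binary predictor '%s' must be 0/1",
                  cohort$id[which(bad)[1]], d$name),
          "oxrecal_cohort_error")
      }
    } else if (!is.numeric(v)) {
      oxrecal_error(sprintf("continuous predictor '%s' must be numeric", d$name),
                    "oxrecal_cohort_error")
    }
  }
  if ("outcome" %in% names(cohort)) {
    bad <- !is.na(cohort$outcome) & !(cohort$outcome %in% c(0, 1))
    if (any(bad)) {
      oxrecal_error("outcome must be 0, 1 or missing", "oxrecal_cohort_error")
    }
    if (!"outcome_available" %in% names(cohort)) {
      cohort$outcome_available <- !is.na(cohort$outcome)
    }
    if (any(cohort$outcome_available & is.na(cohort$outcome))) {
      oxrecal_error("outcome marked available but missing", "oxrecal_cohort_error")
    }
  }
  cohort
}

#' Restrict a cohort to complete cases on the outcome
#'
#' Validation is complete-case: individuals whose 1-year outcome could not be
#' ascertained are excluded before any performance metric is computed.
#'
#' @inheritParams validate_cohort
#' @return The subset of rows with an available outcome.
#' @export
complete_cases <- function(cohort) {
  if (!"outcome" %in% names(cohort)) {
    oxrecal_error("cohort has no outcome column", "oxrecal_cohort_error")
  }
  if (!"outcome_available" %in% names(cohort)) {
    cohort$outcome_available <- !is.na(cohort$outcome)
  }
  cohort[cohort$outcome_available & !is.na(cohort$outcome), , drop = FALSE]
}
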