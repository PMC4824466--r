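# Registry data model: patient-level cohort tables, delimited-text I/O,
# inclusion/exclusion filtering and design-matrix encoding.

#' Covariate levels used throughout the package
#'
#' The registry covariates and their admissible levels. The first level of
#' each factor is the reference level of the case-mix model: female, alert,
#' hemorrhagic, non-smoker, no atrial fibrillation, no diabetes.
#'
#' @format A named list of character vectors.
#' @keywords internal
cohort_levels <- list(
  sex = c("female", "male"),
  consciousness = c("alert", "drowsy", "unconscious"),
  subtype = c("hemorrhagic", "ischemic", "unspecified"),
  smoking = c("no", "yes", "unknown"),
  atrial_fibrillation = c("no", "yes"),
  diabetes = c("no", "yes")
)

cohort_columns <- c(
  "patient_id", "age", "sex", "consciousness", "subtype", "smoking",
  "atrial_fibrillation", "diabetes", "hospital_id", "outcome"
)

#' Construct a cohort table
#'
#' Validates a patient-level data frame and returns a `cohort` object: one
#' row per patient with age, sex, consciousness level at admission, stroke
#' subtype, smoking status, atrial fibrillation, diabetes, a hospital
#' identifier, and a binary outcome (dead or ADL-dependent at three months).
#' Missing values (`NA`) are allowed in the outcome (lost to follow-up) and
#' in covariates; they are handled by [apply_inclusion_criteria()].
#'
#' @param data A data frame with columns `patient_id`, `age`, `sex`,
#'   `consciousness`, `subtype`, `smoking`, `atrial_fibrillation`,
#'   `diabetes`, `hospital_id`, `outcome`. Categorical columns may be
#'   character or factor; levels must be among [cohort_levels].
#' @return A `cohort` object (a validated data frame). The number of
#'   patients and hospitals are available via [cohort_size()].
#' @export
cohort <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[cohort_columns]
  if (nrow(data) < 1L) stop("cohort must contain at least one patient", call. = FALSE)

  data$patient_id <- as.character(data$patient_id)
  data$hospital_id <- as.character(data$hospital_id)
  if (anyNA(data$hospital_id) || any(data$hospital_id == "")) {
    stop("hospital_id must be non-missing for every record", call. = FALSE)
  }
  data$age <- as.numeric(data$age)
  if (any(!is.finite(data$age) & !is.na(data$age))) {
    stop("age must be finite or missing", call. = FALSE)
  }

  for (nm in names(cohort_levels)) {
    data[[nm]] <- validate_levels(data[[nm]], cohort_levels[[nm]], nm)
  }

  out <- suppressWarnings(as.integer(as.character(data$outcome)))
  bad <- which(!is.na(data$outcome) & (is.na(out) | !out %in% c(0L, 1L)))
  if (length(bad) > 0L) {
    stop("outcome must be 0, 1 or missing; offending row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  data$outcome <- out

  rownames(data) <- NULL
  class(data) <- c("cohort", "data.frame")
  data
}

validate_levels <- function(x, levels, name) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  bad <- which(!is.na(x) & !x %in% levels)
  if (length(bad) > 0L) {
    stop(sprintf("unknown level(s) in column '%s' at row(s) %s (allowed: %s)",
                 name, paste(utils::head(bad, 10L), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  factor(x, levels = levels)
}

#' Cohort dimensions
#'
#' @param x A `cohort`.
#' @return A list with `n` (patients) and `m` (distinct hospitals).
#' @export
cohort_size <- function(x) {
  stopifnot(inherits(x, "cohort"))
  list(n = nrow(x), m = length(unique(x$hospital_id)))
}

#' @export
print.cohort <- function(x, ...) {
  sz <- cohort_size(x)
  cat(sprintf("<cohort> %d patients in %d hospitals\n", sz$n, sz$m))
  cat(sprintf("  outcome: %d events, %d non-events, %d missing\n",
              sum(x$outcome == 1L, na.rm = TRUE),
              sum(x$outcome == 0L, na.rm = TRUE), sum(is.na(x$outcome))))
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' Reads a UTF-8 delimited text file (comma by default, tab accepted) with a
#' header row naming the cohort columns. Empty fields and the literal string
#' `NA` are both treated as missing.
#'
#' @param path Path to the file.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = c("", "NA"),
                           quote = "\"", comment.char = "", encoding = "UTF-8",
                           stringsAsFactors = FALSE)
  cohort(raw)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, path))` restores
#' every field exactly, including the binary representation of `age`.
#' Missing values are written as empty fields.
#'
#' @param x A `cohort`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cohort"))
  out <- as.data.frame(x)
  # %.17g keeps doubles bit-exact across the text round trip
  out$age <- ifelse(is.na(out$age), NA, sprintf("%.17g", out$age))
  for (nm in names(out)) out[[nm]] <- as.character(out[[nm]])
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the study inclusion criteria
#'
#' Filters a parsed cohort the way the analysis cohort is defined:
#' \enumerate{
#'   \item Records with missing age or age outside `age_range` are dropped
#'     first; the remainder defines `n_eligible`.
#'   \item Records with a missing outcome are removed and counted as lost to
#'     follow-up.
#'   \item Missing smoking status is recoded to the level `"unknown"` (it is
#'     a recognised level, not missingness).
#'   \item Records with any other missing covariate are removed and counted
#'     as missing-covariate exclusions.
#' }
#'
#' @param x A [cohort()].
#' @param age_range Inclusive age bounds for eligibility, default `c(18, 80)`.
#' @return A list with `cohort` (the included records, order preserved) and
#'   `report`, an `exclusion_report` with fields `n_eligible`,
#'   `n_lost_followup`, `n_missing_covariates`, `n_included`.
#' @export
apply_inclusion_criteria <- function(x, age_range = c(18, 80)) {
  stopifnot(inherits(x, "cohort"), length(age_range) == 2L)
  eligible <- x[!is.na(x$age) & x$age >= age_range[1] & x$age <= age_range[2], ]
  n_eligible <- nrow(eligible)

  has_outcome <- !is.na(eligible$outcome)
  n_lost <- sum(!has_outcome)
  kept <- eligible[has_outcome, ]

  smoking <- as.character(kept$smoking)
  smoking[is.na(smoking)] <- "unknown"
  kept$smoking <- factor(smoking, levels = cohort_levels$smoking)

  covars <- c("sex", "consciousness", "subtype", "atrial_fibrillation", "diabetes")
  complete <- !Reduce(`|`, lapply(kept[covars], is.na))
  n_missing <- sum(!complete)
  kept <- kept[complete, ]
  rownames(kept) <- NULL

  if (nrow(kept) == 0L) stop("no included patients after exclusions", call. = FALSE)

  report <- structure(
    list(n_eligible = n_eligible, n_lost_followup = n_lost,
         n_missing_covariates = n_missing, n_included = nrow(kept)),
    class = "exclusion_report")
  class(kept) <- c("cohort", "data.frame")
  list(cohort = kept, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(format_exclusion_report(x), sep = "\n")
  invisible(x)
}

format_exclusion_report <- function(x) {
  c(sprintf("n_eligible: %d", x$n_eligible),
    sprintf("n_lost_followup: %d", x$n_lost_followup),
    sprintf("n_missing_covariates: %d", x$n_missing_covariates),
    sprintf("n_included: %d", x$n_included))
}

#' Serialize an exclusion report
#'
#' Writes the exclusion counts either as a flat `key: value` text block or
#' as JSON.
#'
#' @param x An `exclusion_report`.
#' @param path Output path.
#' @param format `"text"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(x, path, format = c("text", "json")) {
  stopifnot(inherits(x, "exclusion_report"))
  format <- match.arg(format)
  if (format == "text") {
    writeLines(format_exclusion_report(x), path)
  } else {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE)
  }
  invisible(path)
}
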