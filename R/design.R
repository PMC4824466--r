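# Design-matrix encoding for the fixed-effects logistic model:
# logit(p_i) = beta0 + x_i' beta + sum_{h=2}^m I_h psi_h.

covariate_labels <- c(
  "(Intercept)", "age", "sex=male", "consciousness=drowsy",
  "consciousness=unconscious", "subtype=ischemic", "subtype=unspecified",
  "smoking=yes", "smoking=unknown", "af=yes", "diabetes=yes"
)

# 11-column covariate block (intercept + dummies at the model's reference
# levels) for any data frame holding the cohort covariate columns.
encode_covariates <- function(data) {
  n <- nrow(data)
  X <- cbind(
    1,
    as.numeric(data$age),
    as.numeric(data$sex == "male"),
    as.numeric(data$consciousness == "drowsy"),
    as.numeric(data$consciousness == "unconscious"),
    as.numeric(data$subtype == "ischemic"),
    as.numeric(data$subtype == "unspecified"),
    as.numeric(data$smoking == "yes"),
    as.numeric(data$smoking == "unknown"),
    as.numeric(data$atrial_fibrillation == "yes"),
    as.numeric(data$diabetes == "yes")
  )
  colnames(X) <- covariate_labels
  X
}

# Hospital-indicator block for one hospital level under a given coding:
# the pattern every patient of that hospital carries in the m-1 hospital
# columns (levels 2..m; the lexicographically smallest id is the reference).
hospital_pattern <- function(h_index, m, coding) {
  pat <- numeric(m - 1L)
  if (h_index == 1L) {
    if (coding == "effects") pat[] <- -1
  } else {
    pat[h_index - 1L] <- 1
  }
  pat
}

#' Encode the case-mix design matrix
#'
#' Builds the numeric design matrix of the fixed-effects logistic model:
#' an intercept, the patient covariates dummy-coded at the reference levels
#' female / alert / hemorrhagic / smoking no / AF no / diabetes no, and
#' `m - 1` hospital columns. Hospital identifiers are sorted
#' lexicographically; the smallest is the reference hospital.
#'
#' Under `"reference"` coding the reference hospital has all-zero hospital
#' columns and `psi_h` is a log-odds ratio against that hospital. Under
#' `"effects"` (sum-to-zero) coding the reference hospital is coded −1 in
#' every hospital column, so each exponentiated hospital effect compares the
#' hospital to the average over all hospitals. Both codings span the same
#' column space and give identical fitted risks.
#'
#' @param x A filtered [cohort()] (no missing outcome or covariates).
#' @param coding `"reference"` (default) or `"effects"`.
#' @return A `casemix_design`: list with `X` (numeric matrix), `coding`,
#'   `hospital_ids` (sorted levels), `hospital_index` (per-patient level
#'   index), `outcomes`, and `n_covariates` (number of non-hospital columns).
#' @export
encode_design <- function(x, coding = c("reference", "effects")) {
  stopifnot(inherits(x, "cohort"))
  coding <- match.arg(coding)
  if (anyNA(x$outcome) || anyNA(x$smoking) || anyNA(x$sex) ||
      anyNA(x$consciousness) || anyNA(x$subtype) ||
      anyNA(x$atrial_fibrillation) || anyNA(x$diabetes) || anyNA(x$age)) {
    stop("design encoding requires a filtered cohort; run apply_inclusion_criteria() first",
         call. = FALSE)
  }
  hospital_ids <- sort(unique(x$hospital_id), method = "radix")
  m <- length(hospital_ids)
  if (m < 2L) stop("at least two hospitals are required for a hospital contrast",
                   call. = FALSE)
  h_index <- match(x$hospital_id, hospital_ids)

  Xc <- encode_covariates(x)
  n <- nrow(Xc)
  H <- matrix(0, n, m - 1L)
  for (j in 2:m) H[h_index == j, j - 1L] <- 1
  if (coding == "effects") H[h_index == 1L, ] <- -1
  colnames(H) <- paste0("hospital=", hospital_ids[-1L])

  structure(list(
    X = cbind(Xc, H),
    coding = coding,
    hospital_ids = hospital_ids,
    hospital_index = h_index,
    outcomes = x$outcome,
    n_covariates = ncol(Xc)
  ), class = "casemix_design")
}

#' @export
print.casemix_design <- function(x, ...) {
  cat(sprintf("<casemix_design> %d patients x %d columns (%s coding, %d hospitals)\n",
              nrow(x$X), ncol(x$X), x$coding, length(x$hospital_ids)))
  invisible(x)
}
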