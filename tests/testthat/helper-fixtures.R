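# Shared fixtures: all test data is built in code.

# Deterministic 10-patient, 2-hospital cohort with known missingness:
# rows 3 and 7 lack the outcome, row 5 lacks diabetes, row 9 lacks smoking.
toy_cohort_df <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:10),
    age = c(70, 65, 80, 55, 62, 77, 45, 68, 73, 59),
    sex = rep(c("female", "male"), 5),
    consciousness = c("alert", "alert", "drowsy", "alert", "alert",
                      "unconscious", "alert", "alert", "drowsy", "alert"),
    subtype = c("ischemic", "ischemic", "hemorrhagic", "ischemic", "ischemic",
                "ischemic", "unspecified", "ischemic", "ischemic", "hemorrhagic"),
    smoking = c("no", "yes", "no", "no", "unknown", "no", "yes", "no", NA, "no"),
    atrial_fibrillation = c("no", "no", "yes", "no", "no",
                            "yes", "no", "no", "no", "yes"),
    diabetes = c("no", "yes", "no", "no", NA, "no", "no", "yes", "no", "no"),
    hospital_id = rep(c("A", "B"), each = 5),
    outcome = c(0L, 1L, NA, 0L, 1L, 1L, NA, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# Hand-built design object, for fits on matrices that encode_design cannot
# produce (single hospital, no covariates, ...).
make_design <- function(X, outcomes, hospital_ids, n_covariates,
                        coding = "reference", hospital_index = NULL) {
  structure(list(X = X, coding = coding, hospital_ids = hospital_ids,
                 hospital_index = hospital_index, outcomes = outcomes,
                 n_covariates = n_covariates),
            class = "casemix_design")
}

# Hand-built fit object for arithmetic-level checks (coefficient tables,
# standardization identities) where the coefficients are specified exactly.
make_fit <- function(theta, vcov = diag(length(theta)), n_covariates,
                     hospital_ids, coding = "reference",
                     fitted_risks = numeric(0)) {
  structure(list(theta = theta, vcov = vcov, fitted_risks = fitted_risks,
                 converged = TRUE, penalized = FALSE, loglik = NA_real_,
                 coding = coding, hospital_ids = hospital_ids,
                 n_covariates = n_covariates),
            class = "casemix_fit")
}

# Small synthetic registry for module tests: scaled-down hospital count and
# sizes, same covariate structure and outcome model as the calibrated
# default.
small_registry_config <- function(m = 6, psi = NULL, psi_sd = 0.25,
                                  size_min = 80, size_max = 300) {
  cfg <- default_config_riksstroke()
  generator_config(
    m = m,
    size_law = list(meanlog = log(150), sdlog = 0.4,
                    min = size_min, max = size_max),
    covariate_marginals = cfg$covariate_marginals,
    coefficients = cfg$coefficients,
    psi_law = if (is.null(psi)) list(sd = psi_sd) else list(psi = psi),
    loss_to_followup_rate = 0
  )
}

.registry_cache <- new.env(parent = emptyenv())

# Memoized: generated cohort + reference-coding design + ML fit.
small_fitted_registry <- function(seed = 11, m = 6) {
  key <- sprintf("s%d_m%d", seed, m)
  if (is.null(.registry_cache[[key]])) {
    gen <- generate_cohort(small_registry_config(m = m), seed = seed)
    design <- encode_design(gen$cohort, "reference")
    fit <- fit_casemix_model(design)
    .registry_cache[[key]] <- list(gen = gen, cohort = gen$cohort,
                                   design = design, fit = fit)
  }
  .registry_cache[[key]]
}

# Independent oracle: standardized risks by an explicit double loop over
# patients and hospitals, building each counterfactual design row and
# multiplying by the full coefficient vector.
brute_force_risks <- function(fit, design) {
  theta <- fit$theta
  ncov <- fit$n_covariates
  m <- length(fit$hospital_ids)
  n <- nrow(design$X)
  R <- numeric(m)
  for (h in seq_len(m)) {
    pat <- hospbench:::hospital_pattern(h, m, fit$coding)
    acc <- 0
    for (i in seq_len(n)) {
      row_i <- c(design$X[i, seq_len(ncov)], pat)
      acc <- acc + 1 / (1 + exp(-sum(row_i * theta)))
    }
    R[h] <- acc / n
  }
  R
}
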