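# Fixed-effects multiple logistic regression for case-mix adjustment:
# maximum-likelihood fit (IRLS), observed-information covariance, Firth
# fallback under separation, hospital odds ratios and coefficient tables.

binomial_loglik <- function(y, p) sum(stats::dbinom(y, 1L, p, log = TRUE))

#' Fit the case-mix adjustment model
#'
#' Maximum-likelihood fit of the fixed-effects logistic model
#' `logit(p_i) = beta0 + x_i' beta + psi_h(i)` by iteratively reweighted
#' least squares ([stats::glm.fit()]), followed by a Newton polish so that
#' the score equations hold to near machine precision. The covariance is
#' the inverse observed Fisher information at the optimum.
#'
#' If the fit does not converge or shows signs of separation (any hospital
#' effect beyond `separation_threshold` in absolute value), the model is
#' refitted with Firth's penalized likelihood, which keeps every hospital
#' estimable (e.g. small hospitals with zero events), and the `penalized`
#' flag is set.
#'
#' @param design A `casemix_design` from [encode_design()].
#' @param outcomes Binary outcome vector; defaults to the outcomes carried
#'   by the design.
#' @param start Optional starting coefficient vector (warm start).
#' @param epsilon,maxit Convergence control: relative change threshold and
#'   iteration cap.
#' @param separation_threshold Absolute hospital-effect size beyond which
#'   separation is declared and the Firth fallback used.
#' @return A `casemix_fit`: `theta` (named coefficients), `vcov`,
#'   `fitted_risks`, `converged`, `penalized`, `loglik`, plus the coding and
#'   hospital bookkeeping needed downstream.
#' @export
fit_casemix_model <- function(design, outcomes = design$outcomes, start = NULL,
                              epsilon = 1e-10, maxit = 100L,
                              separation_threshold = 10) {
  stopifnot(inherits(design, "casemix_design"))
  X <- design$X
  y <- as.integer(outcomes)
  if (length(y) != nrow(X)) stop("outcomes do not match the design rows", call. = FALSE)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("outcomes must be 0/1", call. = FALSE)

  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(), start = start,
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  theta <- fit$coefficients
  converged <- isTRUE(fit$converged) && all(is.finite(theta))

  hosp_cols <- if (ncol(X) > design$n_covariates)
    seq.int(design$n_covariates + 1L, ncol(X)) else integer(0)
  separated <- !converged ||
    (length(hosp_cols) > 0L && any(abs(theta[hosp_cols]) > separation_threshold))

  penalized <- FALSE
  if (separated) {
    theta <- fit_firth(X, y, maxit = maxit)
    penalized <- TRUE
    converged <- TRUE
  } else {
    theta <- newton_polish(X, y, theta)
  }

  p <- stats::plogis(drop(X %*% theta))
  w <- p * (1 - p)
  info <- crossprod(X, X * w)
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(theta) <- colnames(X)

  structure(list(
    theta = theta, vcov = vcov, fitted_risks = p,
    converged = converged, penalized = penalized,
    loglik = binomial_loglik(y, p),
    coding = design$coding, hospital_ids = design$hospital_ids,
    n_covariates = design$n_covariates
  ), class = "casemix_fit")
}

# A few Newton steps to drive the score to ~0 beyond glm.fit's deviance-
# based stopping rule (downstream delta-method algebra assumes the score
# equations hold).
newton_polish <- function(X, y, theta, tol = 1e-9, steps = 5L) {
  for (i in seq_len(steps)) {
    p <- stats::plogis(drop(X %*% theta))
    score <- crossprod(X, y - p)
    if (max(abs(score)) < tol) break
    info <- crossprod(X, X * (p * (1 - p)))
    theta <- theta + drop(solve(info, score))
  }
  theta
}

# Firth-penalized logistic regression: Newton iteration on the modified
# score U*(theta) = X'(y - p + h (1/2 - p)), h the leverages of the
# weighted design. Guarantees finite estimates under separation.
fit_firth <- function(X, y, maxit = 100L, tol = 1e-8) {
  theta <- numeric(ncol(X))
  theta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-8), 1e-8))
  pen_ll <- function(th) {
    p <- stats::plogis(drop(X %*% th))
    binomial_loglik(y, p) +
      0.5 * determinant(crossprod(X, X * (p * (1 - p))), logarithm = TRUE)$modulus
  }
  ll_old <- pen_ll(theta)
  for (i in seq_len(maxit)) {
    p <- stats::plogis(drop(X %*% theta))
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    R <- chol(info)
    h <- rowSums((XW %*% backsolve(R, diag(ncol(X))))^2)
    score <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(chol2inv(R) %*% score)
    step <- 1
    repeat {  # step halving keeps the penalized likelihood increasing
      ll_new <- pen_ll(theta + step * delta)
      if (is.finite(ll_new) && (ll_new >= ll_old - 1e-12)) break
      step <- step / 2
      if (step < 1e-6) break
    }
    theta <- theta + step * delta
    if (max(abs(step * delta)) < tol || abs(ll_new - ll_old) < 1e-12) break
    ll_old <- ll_new
  }
  theta
}

# Hospital effects on the log-odds scale for all m hospitals, whatever the
# coding (reference: psi_1 = 0; effects: psi_1 = -sum of the others).
psi_values <- function(fit) {
  stopifnot(inherits(fit, "casemix_fit"))
  psi_cols <- if (length(fit$theta) > fit$n_covariates)
    fit$theta[seq.int(fit$n_covariates + 1L, length(fit$theta))] else numeric(0)
  psi <- if (fit$coding == "reference") c(0, psi_cols) else c(-sum(psi_cols), psi_cols)
  names(psi) <- fit$hospital_ids
  psi
}

#' Counterfactual risk of a patient under a given hospital
#'
#' Evaluates `expit(beta0 + x' beta + psi_h)`: the fitted risk patient `x`
#' would have under hospital `h`'s level of care, regardless of where the
#' patient was actually treated.
#'
#' @param fit A `casemix_fit`.
#' @param record A one-row data frame (or [cohort()] row) with the
#'   covariate columns.
#' @param hospital A fitted hospital id.
#' @return A probability.
#' @export
predict_risk <- function(fit, record, hospital) {
  stopifnot(inherits(fit, "casemix_fit"))
  psi <- psi_values(fit)
  if (!hospital %in% names(psi)) stop("unknown hospital id: ", hospital, call. = FALSE)
  x <- encode_covariates(as.data.frame(record))
  beta <- fit$theta[seq_len(fit$n_covariates)]
  stats::plogis(drop(x %*% beta) + psi[[hospital]])
}

#' Hospital odds ratios versus the average hospital
#'
#' `OR_h = exp(psi_h - mean(psi))`, the exponentiated sum-to-zero (effects
#' coded) hospital effect: each hospital's odds of the outcome relative to
#' the average over all hospitals, after case-mix adjustment. The geometric
#' mean of the returned odds ratios is 1 by construction.
#'
#' @param fit A `casemix_fit`.
#' @return Named numeric vector of odds ratios, one per hospital.
#' @export
hospital_or_vs_average <- function(fit) {
  psi <- psi_values(fit)
  exp(psi - mean(psi))
}

#' Coefficient table with odds ratios and confidence intervals
#'
#' Summarises a fit as estimate, standard error, odds ratio
#' `OR = exp(estimate)`, 95% Wald confidence interval
#' `exp(estimate ± 1.96 SE)` and two-sided Wald p-value per coefficient.
#' When the design and outcomes are supplied, each multi-level covariate
#' factor additionally gets a likelihood-ratio p-value for dropping the
#' whole factor, attached as the `factor_tests` attribute.
#'
#' @param fit A `casemix_fit`.
#' @param design,outcomes Optional: the design and outcomes the fit was
#'   computed on, enabling the factor likelihood-ratio tests.
#' @param include_hospitals Include the hospital-effect rows (default
#'   `FALSE`: covariate rows only, as usually reported).
#' @return A data frame with columns `term`, `estimate`, `se`, `or`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
coefficient_table <- function(fit, design = NULL, outcomes = NULL,
                              include_hospitals = FALSE) {
  stopifnot(inherits(fit, "casemix_fit"))
  idx <- if (include_hospitals) seq_along(fit$theta) else seq_len(fit$n_covariates)
  est <- fit$theta[idx]
  se <- sqrt(diag(fit$vcov))[idx]
  z <- est / se
  tab <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    or = unname(exp(est)),
    ci_lower = unname(exp(est - 1.96 * se)),
    ci_upper = unname(exp(est + 1.96 * se)),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  if (!is.null(design)) {
    if (is.null(outcomes)) outcomes <- design$outcomes
    attr(tab, "factor_tests") <- factor_lr_tests(fit, design, outcomes)
  }
  tab
}

# Likelihood-ratio test for dropping each covariate factor as a whole.
factor_lr_tests <- function(fit, design, outcomes) {
  groups <- list(
    age = 2L, sex = 3L, consciousness = c(4L, 5L), subtype = c(6L, 7L),
    smoking = c(8L, 9L), atrial_fibrillation = 10L, diabetes = 11L
  )
  y <- as.integer(outcomes)
  res <- lapply(names(groups), function(g) {
    keep <- setdiff(seq_len(ncol(design$X)), groups[[g]])
    red <- suppressWarnings(stats::glm.fit(
      design$X[, keep, drop = FALSE], y, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-10, maxit = 100L)))
    lr <- 2 * (fit$loglik - binomial_loglik(y, red$fitted.values))
    df <- length(groups[[g]])
    data.frame(factor = g, df = df, lr_statistic = lr,
               p_value = stats::pchisq(lr, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Export a coefficient table as delimited text
#'
#' @param tab A data frame from [coefficient_table()].
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(tab, path, sep = ",") {
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.casemix_fit <- function(x, ...) {
  cat(sprintf("<casemix_fit> %d coefficients (%s coding, %d hospitals)\n",
              length(x$theta), x$coding, length(x$hospital_ids)))
  cat(sprintf("  log-likelihood %.3f; converged: %s; Firth penalty: %s\n",
              x$loglik, x$converged, x$penalized))
  invisible(x)
}
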