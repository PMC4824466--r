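# Direct standardization: hospital-specific standardized risks over the
# whole included population, delta-method standard errors, and one-sided
# lower confidence bounds.

#' Directly standardized hospital risks
#'
#' For every hospital `h`, the standardized risk is
#' `R_h = (1/n) * sum_i expit(beta0 + x_i' beta + psi_h)` over *all* `n`
#' included patients regardless of where they were treated: the estimated
#' proportion of the whole population that would be dead or ADL-dependent
#' had everyone received hospital `h`'s level of care. Standard errors come
#' from the delta method over the coefficient covariance (see
#' [delta_method_se()]).
#'
#' @param fit A `casemix_fit`.
#' @param design The `casemix_design` the fit was computed on.
#' @return A `standardized_risks` data frame with columns `hospital_id`,
#'   `R`, `SE`, and attributes `population_risk` (the crude observed event
#'   proportion among included patients) and `n` (population size).
#' @export
standardized_risks <- function(fit, design) {
  stopifnot(inherits(fit, "casemix_fit"), inherits(design, "casemix_design"))
  parts <- risk_and_gradient(fit, design)
  V <- fit$vcov
  variances <- colSums((V %*% parts$G) * parts$G)
  if (any(variances <= 0)) {
    stop("coefficient covariance is not positive definite", call. = FALSE)
  }
  out <- data.frame(
    hospital_id = fit$hospital_ids,
    R = parts$R,
    SE = sqrt(variances),
    stringsAsFactors = FALSE
  )
  attr(out, "population_risk") <- mean(design$outcomes)
  attr(out, "n") <- nrow(design$X)
  class(out) <- c("standardized_risks", "data.frame")
  out
}

# Standardized risks plus the delta-method gradient of each R_h with
# respect to the full coefficient vector. Column h of G is
# (1/n) sum_i p_ih (1 - p_ih) x_i(h), where x_i(h) is patient i's design
# row with the hospital block replaced by hospital h's pattern.
risk_and_gradient <- function(fit, design) {
  ncov <- fit$n_covariates
  Xcov <- design$X[, seq_len(ncov), drop = FALSE]
  beta <- fit$theta[seq_len(ncov)]
  eta_cov <- drop(Xcov %*% beta)
  psi <- psi_values(fit)
  m <- length(psi)
  n <- nrow(Xcov)
  p_total <- length(fit$theta)

  R <- numeric(m)
  G <- matrix(0, p_total, m)
  for (h in seq_len(m)) {
    p_ih <- stats::plogis(eta_cov + psi[h])
    w <- p_ih * (1 - p_ih)
    R[h] <- mean(p_ih)
    g_cov <- crossprod(Xcov, w) / n
    g_hosp <- hospital_pattern(h, m, fit$coding) * mean(w)
    G[, h] <- c(g_cov, g_hosp)
  }
  list(R = R, G = G, psi = psi)
}

#' Delta-method standard error of one standardized risk
#'
#' Standard error of `R_h` from the first-order (delta-method) expansion
#' around the maximum-likelihood estimate: with gradient
#' `g_h = (1/n) sum_i p_ih (1 - p_ih) x_i(h)`,
#' `Var(R_h) = g_h' Cov(theta) g_h`. In the intercept-only single-hospital
#' case this collapses to the binomial proportion variance `p(1-p)/n`.
#'
#' @param fit A `casemix_fit`.
#' @param design The matching `casemix_design`.
#' @param hospital A fitted hospital id.
#' @return The standard error (positive scalar).
#' @export
delta_method_se <- function(fit, design, hospital) {
  stopifnot(inherits(fit, "casemix_fit"))
  h <- match(hospital, fit$hospital_ids)
  if (is.na(h)) stop("unknown hospital id: ", hospital, call. = FALSE)
  parts <- risk_and_gradient(fit, design)
  g <- parts$G[, h]
  v <- drop(crossprod(g, fit$vcov %*% g))
  if (v <= 0) stop("coefficient covariance is not positive definite", call. = FALSE)
  sqrt(v)
}

#' One-sided lower confidence bound for a standardized risk
#'
#' Normal-approximation bound `R - qnorm(k) * SE`: we are `k x 100%`
#' confident that the true standardized risk exceeds this value. At
#' `k = 0.5` the bound equals `R` itself. The bound is not clipped at zero;
#' it is only ever compared against a benchmark.
#'
#' @param R Standardized risk(s).
#' @param SE Standard error(s), positive.
#' @param k One-sided confidence level in (0, 1).
#' @return Numeric vector of lower bounds.
#' @export
one_sided_lower_bound <- function(R, SE, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k >= 1) {
    stop("k must be a single number strictly between 0 and 1", call. = FALSE)
  }
  R - stats::qnorm(k) * SE
}

#' @export
print.standardized_risks <- function(x, ...) {
  cat(sprintf("<standardized_risks> %d hospitals; population risk %.4f (n = %d)\n",
              nrow(x), attr(x, "population_risk"), attr(x, "n")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Read / write standardized risk sets
#'
#' Delimited-text export of a [standardized_risks()] table: `hospital_id`,
#' `R`, `SE`, plus `lower_bound` for a requested confidence level `k`.
#' This file format is also the hospital-risk input of the ROC planner
#' ([theoretical_roc()]); `read_risks()` restores the table and its
#' `population_risk` / `n` attributes from the header comment when present.
#'
#' @param x A `standardized_risks` data frame.
#' @param path File path.
#' @param k Optional confidence level adding a `lower_bound` column.
#' @param sep Field delimiter.
#' @return `write_risks` returns `path` invisibly; `read_risks` returns a
#'   `standardized_risks` data frame.
#' @export
write_risks <- function(x, path, k = NULL, sep = ",") {
  stopifnot(inherits(x, "standardized_risks"))
  out <- as.data.frame(x)
  if (!is.null(k)) out$lower_bound <- one_sided_lower_bound(out$R, out$SE, k)
  for (nm in c("R", "SE", "lower_bound")) {
    if (nm %in% names(out)) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# population_risk=%.17g n=%d",
                     attr(x, "population_risk"), attr(x, "n")), con)
  utils::write.table(out, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_risks
#' @export
read_risks <- function(path, sep = ",") {
  header <- readLines(path, n = 1L)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$hospital_id <- as.character(tab$hospital_id)
  pat <- "^# population_risk=([^ ]+) n=([0-9]+)$"
  if (grepl(pat, header)) {
    attr(tab, "population_risk") <- as.numeric(sub(pat, "\\1", header))
    attr(tab, "n") <- as.integer(sub(pat, "\\2", header))
  }
  class(tab) <- c("standardized_risks", "data.frame")
  tab
}
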