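test_that("maximum-likelihood estimates match closed forms on 2x2 tables", {
  # one hospital, intercept only: MLE of a proportion
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(1L, 0L), c(25, 75))
  d <- make_design(X, y, hospital_ids = "H1", n_covariates = 1)
  fit <- fit_casemix_model(d)
  expect_equal(unname(fit$theta), log(25 / 75), tolerance = 1e-8)
  expect_false(fit$penalized)

  # two hospitals, no covariates: psi_2 is the 2x2-table log odds ratio
  X2 <- cbind("(Intercept)" = 1, "hospital=H2" = rep(c(0, 1), each = 100))
  y2 <- c(rep(c(1L, 0L), c(10, 90)), rep(c(1L, 0L), c(20, 80)))
  d2 <- make_design(X2, y2, hospital_ids = c("H1", "H2"), n_covariates = 1)
  fit2 <- fit_casemix_model(d2)
  expect_equal(unname(fit2$theta["hospital=H2"]),
               log((20 / 80) / (10 / 90)), tolerance = 1e-8)
  expect_equal(round(unname(fit2$theta["hospital=H2"]), 4), 0.8109)
})

test_that("score equations vanish at the optimum", {
  reg <- small_fitted_registry()
  score <- crossprod(reg$design$X, reg$design$outcomes - reg$fit$fitted_risks)
  expect_lt(max(abs(score)), 1e-6)
})

test_that("reference and effects codings give identical fitted risks", {
  reg <- small_fitted_registry()
  de <- encode_design(reg$cohort, "effects")
  fe <- fit_casemix_model(de)
  expect_lt(max(abs(fe$fitted_risks - reg$fit$fitted_risks)), 1e-8)
  # and the same hospital odds ratios versus the average
  expect_equal(hospital_or_vs_average(fe), hospital_or_vs_average(reg$fit),
               tolerance = 1e-6)
})

test_that("covariance matches a numerically differentiated Hessian", {
  set.seed(31)
  n <- 250
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- rbinom(n, 1, plogis(drop(X %*% c(-0.5, 0.7, -0.4))))
  d <- make_design(X, y, hospital_ids = "H1", n_covariates = 3)
  fit <- fit_casemix_model(d)

  ll <- function(th) sum(dbinom(y, 1, plogis(drop(X %*% th)), log = TRUE))
  h <- 1e-3
  p <- length(fit$theta)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- ej <- numeric(p); ei[i] <- h; ej[j] <- h
    H[i, j] <- (ll(fit$theta + ei + ej) - ll(fit$theta + ei - ej) -
                ll(fit$theta - ei + ej) + ll(fit$theta - ei - ej)) / (4 * h^2)
  }
  V_num <- solve(-H)
  expect_lt(max(abs(V_num - fit$vcov)) / max(abs(fit$vcov)), 1e-4)
})

test_that("separation triggers the Firth fallback with finite estimates", {
  set.seed(17)
  X <- cbind("(Intercept)" = 1, "hospital=H2" = rep(c(0, 1), c(150, 30)))
  y <- c(rbinom(150, 1, 0.25), rep(0L, 30))  # zero events in hospital 2
  d <- make_design(X, y, hospital_ids = c("H1", "H2"), n_covariates = 1)
  fit <- fit_casemix_model(d)
  expect_true(fit$penalized)
  expect_true(all(is.finite(fit$theta)))
  expect_true(all(is.finite(sqrt(diag(fit$vcov)))))
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  X <- cbind("(Intercept)" = 1, "age" = rnorm(50), "age_copy" = 0)
  X[, 3] <- X[, 2]
  d <- make_design(X, rbinom(50, 1, 0.3), hospital_ids = "H1", n_covariates = 3)
  expect_error(fit_casemix_model(d), "age_copy|age")
})

test_that("counterfactual risk prediction follows the linear predictor", {
  reg <- small_fitted_registry()
  fit <- reg$fit
  psi <- hospbench:::psi_values(fit)
  rec <- reg$cohort[1, ]
  # reproduce expit(x'beta + psi_h) for every hospital, monotone in psi
  risks <- vapply(names(psi), function(h) predict_risk(fit, rec, h), numeric(1))
  expect_equal(order(risks), order(psi))
  beta <- fit$theta[1:fit$n_covariates]
  eta <- drop(hospbench:::encode_covariates(rec) %*% beta)
  expect_equal(unname(risks[1]), plogis(eta + psi[[1]]), tolerance = 1e-12)
  expect_error(predict_risk(fit, rec, "NOPE"), "unknown hospital")
  expect_equal(plogis(0.5), 0.6225, tolerance = 1e-4)
})

test_that("hospital odds ratios are centered on their geometric mean", {
  fit <- make_fit(theta = c("(Intercept)" = -1, "hospital=H2" = 0.2),
                  n_covariates = 1, hospital_ids = c("H1", "H2"))
  expect_equal(unname(hospital_or_vs_average(fit)),
               c(exp(-0.1), exp(0.1)), tolerance = 1e-12)
  fit_eq <- make_fit(theta = c("(Intercept)" = -1, "hospital=H2" = 0,
                               "hospital=H3" = 0),
                     n_covariates = 1, hospital_ids = c("H1", "H2", "H3"))
  expect_equal(unname(hospital_or_vs_average(fit_eq)), rep(1, 3))
  reg <- small_fitted_registry()
  expect_equal(exp(mean(log(hospital_or_vs_average(reg$fit)))), 1,
               tolerance = 1e-12)
})

test_that("coefficient tables compute ORs, Wald CIs and factor LR tests", {
  fit <- make_fit(theta = c("(Intercept)" = 0, "x" = 0),
                  vcov = diag(c(0.04, 0.01)),
                  n_covariates = 2, hospital_ids = "H1")
  tab <- coefficient_table(fit)
  expect_equal(tab$or[2], 1.0)
  expect_equal(tab$ci_lower[2] * tab$ci_upper[2], 1.0, tolerance = 1e-12)

  reg <- small_fitted_registry()
  tab2 <- coefficient_table(reg$fit, design = reg$design)
  expect_equal(tab2$or, exp(tab2$estimate))
  expect_equal(tab2$ci_upper, exp(tab2$estimate + 1.96 * tab2$se))
  ft <- attr(tab2, "factor_tests")
  expect_equal(nrow(ft), 7L)
  expect_equal(ft$df[ft$factor == "consciousness"], 2L)
  expect_true(all(ft$p_value >= 0 & ft$p_value <= 1))
  # strong effects in the generating model must be detected at this n
  expect_lt(ft$p_value[ft$factor == "consciousness"], 1e-6)
})
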