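test_that("calibrated default configuration carries the published marginals and coefficients", {
  cfg <- default_config_riksstroke()
  expect_equal(cfg$m, 76L)
  expect_equal(cfg$covariate_marginals$age_mean, 67.6)
  expect_equal(unname(cfg$covariate_marginals$diabetes["yes"]), 0.196)
  expect_equal(unname(cfg$covariate_marginals$sex["male"]), 0.589)
  expect_equal(unname(cfg$coefficients["age"]), 0.048)
  expect_equal(unname(cfg$coefficients["(Intercept)"]), -4.495)
  expect_equal(cfg$psi_law$sd, 0.25)
})

test_that("generation is deterministic in (config, seed) and respects the loss rate", {
  cfg <- small_registry_config(m = 4)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(as.data.frame(a$cohort), as.data.frame(c2$cohort)))
  expect_false(anyNA(a$cohort$outcome))  # loss_to_followup_rate = 0

  cfg2 <- cfg; cfg2$loss_to_followup_rate <- 0.13
  d <- generate_cohort(cfg2, seed = 5)
  frac <- mean(is.na(d$cohort$outcome))
  n <- nrow(d$cohort)
  expect_gt(frac, 0.13 - 3 * sqrt(0.13 * 0.87 / n))
  expect_lt(frac, 0.13 + 3 * sqrt(0.13 * 0.87 / n))
})

test_that("adding hospitals does not reshuffle earlier hospitals' patients", {
  a <- generate_cohort(small_registry_config(m = 4), seed = 9)$cohort
  b <- generate_cohort(small_registry_config(m = 6), seed = 9)$cohort
  a4 <- a[a$hospital_id %in% sprintf("H%02d", 1:4), ]
  b4 <- b[b$hospital_id %in% sprintf("H%02d", 1:4), ]
  expect_identical(as.data.frame(a4), as.data.frame(b4))
})

test_that("generated marginals match the configuration within binomial tolerance", {
  cfg <- default_config_riksstroke()
  x <- generate_cohort(cfg, seed = 21)$cohort
  expect_gte(nrow(x), 10000)
  for (nm in c("sex", "consciousness", "subtype", "smoking",
               "atrial_fibrillation", "diabetes")) {
    observed <- prop.table(table(x[[nm]]))
    expected <- cfg$covariate_marginals[[nm]]
    expect_true(all(abs(observed[names(expected)] - expected) < 0.02),
                label = sprintf("marginal calibration for %s", nm))
  }
  expect_true(all(x$age >= 18 & x$age <= 80))
  # pooled event rate near the calibration anchor of ~22%
  expect_gt(mean(x$outcome), 0.19)
  expect_lt(mean(x$outcome), 0.25)
})

test_that("true standardized risks obey the closed-form and monotonicity properties", {
  cfg <- small_registry_config(m = 2)
  # single patient whose linear predictor is 0 under psi = 0
  rec <- data.frame(age = 4.495 / 0.048, sex = "female", consciousness = "alert",
                    subtype = "hemorrhagic", smoking = "no",
                    atrial_fibrillation = "no", diabetes = "no")
  ts <- true_standardized_risks(cfg, c(0, 0), rec)
  expect_equal(ts$true_Rh, c(0.5, 0.5), tolerance = 1e-12)

  # two patients with linear predictors 0 and 1, psi = 0.5
  cfg1 <- cfg; cfg1$coefficients[] <- 0; cfg1$coefficients["age"] <- 1
  recs <- data.frame(age = c(0, 1), sex = "female", consciousness = "alert",
                     subtype = "hemorrhagic", smoking = "no",
                     atrial_fibrillation = "no", diabetes = "no")
  ts2 <- true_standardized_risks(cfg1, c(0.5, 0), recs)
  expect_equal(ts2$true_Rh[1], (plogis(0.5) + plogis(1.5)) / 2, tolerance = 1e-12)
  expect_equal(round(ts2$true_Rh[1], 4), 0.7200)

  # strictly increasing in psi, componentwise
  base <- generate_cohort(small_registry_config(m = 3), seed = 2)
  psi <- base$truth$psi
  shifted <- true_standardized_risks(small_registry_config(m = 3), psi + 0.01,
                                     base$cohort)
  expect_true(all(shifted$true_Rh > base$truth$true_Rh))
})

test_that("zero hospital-effect spread gives identical true risks", {
  cfg <- small_registry_config(m = 5, psi_sd = 0)
  gen <- generate_cohort(cfg, seed = 4)
  expect_equal(gen$truth$psi, rep(0, 5))
  expect_equal(diff(range(gen$truth$true_Rh)), 0)
})

test_that("generator configuration round-trips through YAML", {
  cfg <- small_registry_config(m = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$coefficients, cfg$coefficients)
  expect_equal(cfg2$covariate_marginals, cfg$covariate_marginals)
  expect_equal(cfg2$m, cfg$m)
  expect_identical(as.data.frame(generate_cohort(cfg, seed = 3)$cohort),
                   as.data.frame(generate_cohort(cfg2, seed = 3)$cohort))
})

test_that("degenerate generator configurations are rejected", {
  cfg <- small_registry_config(m = 3)
  expect_error(generator_config(m = 3, size_law = cfg$size_law,
                                covariate_marginals = cfg$covariate_marginals,
                                coefficients = cfg$coefficients,
                                psi_law = list(sd = -1)), "sd")
  bad <- cfg$covariate_marginals; bad$sex <- c(female = -0.2, male = 1.2)
  expect_error(generator_config(m = 3, size_law = cfg$size_law,
                                covariate_marginals = bad,
                                coefficients = cfg$coefficients,
                                psi_law = list(sd = 0.2)), "sex")
  expect_error(generate_cohort(cfg, seed = NULL), "seed")
})
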