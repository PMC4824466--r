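test_that("flag probability follows the normal sampling model", {
  # a hospital exactly at the benchmark is flagged with probability 1 - k
  for (k in c(0.1, 0.5, 0.9)) {
    expect_equal(flag_probability(0.25, 0.03, 0.25, k), 1 - k, tolerance = 1e-12)
  }
  expect_equal(flag_probability(0.28, 0.03, 0.25, 0.99),
               pnorm(1 - qnorm(0.99)), tolerance = 1e-12)
  expect_equal(flag_probability(0.28, 0.03, 0.25, 0.99), 0.0923, tolerance = 2e-3)

  # strictly decreasing in k, strictly increasing in (R - B)/SE
  ks <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(flag_probability(0.3, 0.02, 0.28, ks)) < 0))
  zs <- seq(-2, 2, 0.25)
  expect_true(all(diff(pnorm(zs - qnorm(0.7))) > 0))
  expect_error(flag_probability(0.3, -0.1, 0.25, 0.5), "positive")
  expect_error(flag_probability(0.3, 0.02, 0.25, 1), "k must")
})

test_that("flag probability agrees with direct Monte-Carlo application of the rule", {
  set.seed(55)
  R <- 0.27; SE <- 0.025; B <- 0.26; k <- 0.8
  draws <- rnorm(1e5, R, SE)
  flagged <- mean(one_sided_lower_bound(draws, SE, k) > B)
  p <- flag_probability(R, SE, B, k)
  mc_se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(flagged - p), 3 * mc_se)
})

test_that("theoretical ROC classifies by point estimate and averages flag probabilities", {
  risks <- data.frame(hospital_id = sprintf("H%d", 1:4),
                      R = c(0.18, 0.22, 0.30, 0.35),
                      SE = c(0.02, 0.02, 0.02, 0.05))
  input <- planner_input(risks, delta = 0.1, k_grid = c(0.1, 0.5, 0.9, 0.99),
                         population_risk = 0.22)
  curve <- theoretical_roc(input)
  expect_equal(unname(curve$truth), c(FALSE, FALSE, TRUE, TRUE))  # B = 0.242
  expect_equal(curve$benchmark, 0.242)
  k5 <- which(curve$curve$k == 0.5)
  expect_equal(curve$curve$sensitivity[k5],
               mean(pnorm((risks$R[3:4] - 0.242) / risks$SE[3:4])),
               tolerance = 1e-12)

  # single excess hospital at (R - B)/SE = 3: sensitivity at k = 0.5 is pnorm(3)
  one <- data.frame(hospital_id = c("lo", "hi"), R = c(0.20, 0.302),
                    SE = c(0.02, 0.02))
  cv <- theoretical_roc(planner_input(one, delta = 0, k_grid = 0.5,
                                      population_risk = 0.242))
  expect_equal(cv$curve$sensitivity, pnorm(3), tolerance = 1e-10)
  expect_equal(round(cv$curve$sensitivity, 4), 0.9987)

  # endpoint behaviour: k -> 1 drives sensitivity to 0 and specificity to 1
  ends <- theoretical_roc(planner_input(risks, delta = 0.1,
                                        k_grid = c(0.5, 1 - 1e-12),
                                        population_risk = 0.22))
  expect_lt(ends$curve$sensitivity[2], 1e-4)
  expect_gt(ends$curve$specificity[2], 1 - 1e-4)
  expect_true(all(diff(ends$curve$sensitivity) < 0))
  expect_true(all(diff(ends$curve$specificity) > 0))
})

test_that("an empty class yields the undefined marker, and SE -> 0 recovers the deterministic rule", {
  allhi <- data.frame(hospital_id = c("A", "B"), R = c(0.4, 0.45), SE = 0.02)
  cv <- theoretical_roc(planner_input(allhi, delta = 0, k_grid = 0.5,
                                      population_risk = 0.22))
  expect_true(is.na(cv$curve$specificity))
  expect_false(is.na(cv$curve$sensitivity))

  # with tiny SE decisions are deterministic and match compute_diagnostics
  risks <- data.frame(hospital_id = sprintf("H%d", 1:6),
                      R = c(0.15, 0.20, 0.24, 0.26, 0.30, 0.36),
                      SE = 1e-10)
  input <- planner_input(risks, delta = 0.1, k_grid = 0.7,
                         population_risk = 0.22)
  cv2 <- theoretical_roc(input)
  dec <- classify_hospitals(risks, delta = 0.1, k = 0.7, population_risk = 0.22)
  truth <- gold_standard_labels(risks, 0.1, population_risk = 0.22)
  dg <- compute_diagnostics(dec$outlying, truth)
  expect_equal(cv2$curve$sensitivity, dg$sensitivity, tolerance = 1e-9)
  expect_equal(cv2$curve$specificity, dg$specificity, tolerance = 1e-9)
})

test_that("planner export writes one row per k with per-hospital flag probabilities", {
  risks <- data.frame(hospital_id = c("A", "B", "C"),
                      R = c(0.18, 0.26, 0.33), SE = c(0.02, 0.03, 0.04))
  curve <- theoretical_roc(planner_input(risks, delta = 0.1,
                                         k_grid = c(0.25, 0.5, 0.75, 0.95),
                                         population_risk = 0.22))
  path <- withr::local_tempfile(fileext = ".csv")
  export_planner(curve, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("flag_prob_A", "flag_prob_B", "flag_prob_C") %in% names(tab)))
  expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 1))
  expect_true(all(diff(tab$sensitivity) <= 0))
  expect_true(all(diff(tab$specificity) >= 0))
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_planner(curve, path2)
  expect_identical(readLines(path), readLines(path2))

  # round trip via the risk-set reader: planner consumes the standardization export
  reg <- small_fitted_registry()
  rs <- standardized_risks(reg$fit, reg$design)
  rp <- withr::local_tempfile(fileext = ".csv")
  write_risks(rs, rp)
  back <- read_risks(rp)
  input <- planner_input(back, delta = 0.1)
  expect_equal(input$population_risk, attr(rs, "population_risk"))
})
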