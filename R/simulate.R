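# Parametric-bootstrap simulation study: resample outcomes at the fitted
# risks, refit the case-mix model, re-classify against each replicate's own
# benchmark, and tabulate the decision rule's diagnostic properties over a
# (delta, k) grid.

#' Simulation plan
#'
#' @param S Number of bootstrap replicates (the full-scale study uses 1000).
#' @param delta_grid Benchmark margins to evaluate.
#' @param k_grid One-sided confidence levels to evaluate.
#' @param seed Integer root seed; per-replicate seeds are derived from it by
#'   counter, so extending `S` re-uses the earlier replicates' draws.
#' @param record_per_replicate Keep per-replicate population risks and flag
#'   arrays in the result (memory permitting).
#' @return A `simulation_plan` list.
#' @export
simulation_plan <- function(S = 1000L, delta_grid = c(0, 0.10, 0.15, 0.20),
                            k_grid = c(0.10, 0.30, 0.50, 0.75, 0.90, 0.95, 0.99),
                            seed = NULL, record_per_replicate = FALSE) {
  stopifnot(S >= 1, length(delta_grid) >= 1, length(k_grid) >= 1,
            all(k_grid > 0 & k_grid < 1), all(delta_grid >= -1))
  structure(list(S = as.integer(S), delta_grid = delta_grid, k_grid = k_grid,
                 seed = seed, record_per_replicate = record_per_replicate),
            class = "simulation_plan")
}

#' Simulate outcomes from fitted risks
#'
#' Draws one parametric-bootstrap outcome vector: independent
#' `y*_i ~ Bernoulli(p_i)` at the fitted risks, every patient keeping their
#' covariates and actual hospital.
#'
#' @param fit A `casemix_fit`.
#' @param seed Integer seed.
#' @return Integer 0/1 vector of length `n`.
#' @export
simulate_outcomes <- function(fit, seed) {
  stopifnot(inherits(fit, "casemix_fit"))
  set.seed(seed)
  stats::rbinom(length(fit$fitted_risks), 1L, fit$fitted_risks)
}

#' Run the parametric-bootstrap simulation study
#'
#' For each replicate: outcomes are redrawn at the original fitted risks
#' (covariates and hospital assignments held fixed), the replicate's crude
#' population risk defines its own benchmark for every `delta`, the model
#' is refitted (warm-started at the original optimum, with the Firth
#' fallback under separation), standardized risks and standard errors are
#' recomputed, and every `(delta, k)` cell classifies the hospitals. All
#' hospital-by-replicate decisions are scored against gold-standard labels
#' computed once from the original fit and the *original* population risk.
#'
#' @param cohort The included [cohort()] the fit was computed on.
#' @param fit The original `casemix_fit`.
#' @param plan A [simulation_plan()]; its `seed` must be set.
#' @return A `diagnostic_grid`: `cells` (long data frame with sensitivity,
#'   specificity, PPV, NPV, percent correct, the pooled 2x2 counts and
#'   binomial Monte-Carlo standard errors per `(delta, k)`),
#'   `truth_counts` (true-excess hospitals per `delta`),
#'   `n_penalized_refits`, `n_failed_replicates`, `S`, `m`, and — when
#'   `plan$record_per_replicate` — the per-replicate population risks and
#'   flag arrays.
#' @export
run_simulation_study <- function(cohort, fit, plan) {
  stopifnot(inherits(cohort, "cohort"), inherits(fit, "casemix_fit"),
            inherits(plan, "simulation_plan"))
  if (is.null(plan$seed)) stop("the simulation plan needs a seed", call. = FALSE)
  design <- encode_design(cohort, fit$coding)
  if (nrow(design$X) != length(fit$fitted_risks)) {
    stop("fit does not match the cohort", call. = FALSE)
  }

  original_risks <- standardized_risks(fit, design)
  original_pop_risk <- attr(original_risks, "population_risk")
  truth <- lapply(plan$delta_grid, function(d) {
    gold_standard_labels(original_risks, d, population_risk = original_pop_risk)
  })
  names(truth) <- as.character(plan$delta_grid)

  S <- plan$S
  m <- length(fit$hospital_ids)
  nd <- length(plan$delta_grid)
  nk <- length(plan$k_grid)
  set.seed(plan$seed)
  replicate_seeds <- sample.int(.Machine$integer.max - 1L, S)

  flags <- array(NA, dim = c(S, m, nd, nk))
  pop_risks <- rep(NA_real_, S)
  n_penalized <- 0L
  failed <- integer(0)

  for (s in seq_len(S)) {
    y_s <- simulate_outcomes(fit, replicate_seeds[s])
    refit <- tryCatch(
      fit_casemix_model(design, outcomes = y_s, start = fit$theta),
      error = function(e) NULL)
    if (is.null(refit)) {
      failed <- c(failed, s)
      next
    }
    if (refit$penalized) n_penalized <- n_penalized + 1L
    parts <- risk_and_gradient(refit, design)
    se_s <- sqrt(colSums((refit$vcov %*% parts$G) * parts$G))
    pop_risks[s] <- mean(y_s)
    for (di in seq_len(nd)) {
      B_s <- benchmark_value(pop_risks[s], plan$delta_grid[di])
      for (ki in seq_len(nk)) {
        lb <- one_sided_lower_bound(parts$R, se_s, plan$k_grid[ki])
        flags[s, , di, ki] <- lb > B_s
      }
    }
  }

  ok <- setdiff(seq_len(S), failed)
  cells <- vector("list", nd * nk)
  i <- 0L
  for (di in seq_len(nd)) {
    tr <- truth[[di]]
    n_true <- sum(tr)
    for (ki in seq_len(nk)) {
      dg <- compute_diagnostics(flags[ok, , di, ki, drop = TRUE], tr)
      mc_se <- function(v, cls) {
        if (is.na(v) || cls == 0L) NA_real_ else sqrt(v * (1 - v) / (length(ok) * cls))
      }
      i <- i + 1L
      cells[[i]] <- data.frame(
        delta = plan$delta_grid[di], k = plan$k_grid[ki],
        sensitivity = dg$sensitivity, specificity = dg$specificity,
        ppv = dg$ppv, npv = dg$npv, percent_correct = dg$percent_correct,
        tp = dg$counts[["TP"]], fp = dg$counts[["FP"]],
        tn = dg$counts[["TN"]], fn = dg$counts[["FN"]],
        mc_se_sensitivity = mc_se(dg$sensitivity, n_true),
        mc_se_specificity = mc_se(dg$specificity, m - n_true)
      )
    }
  }

  out <- list(
    cells = do.call(rbind, cells),
    truth = truth,
    truth_counts = stats::setNames(vapply(truth, sum, integer(1)),
                                   names(truth)),
    n_penalized_refits = n_penalized,
    n_failed_replicates = length(failed),
    S = S, m = m,
    original_population_risk = original_pop_risk,
    original_risks = original_risks,
    seed = plan$seed
  )
  if (plan$record_per_replicate) {
    out$population_risks <- pop_risks
    out$flags <- flags
  }
  structure(out, class = "diagnostic_grid")
}

#' @export
print.diagnostic_grid <- function(x, ...) {
  cat(sprintf("<diagnostic_grid> %d replicates x %d hospitals; %d (delta, k) cells\n",
              x$S, x$m, nrow(x$cells)))
  cat(sprintf("  penalized refits: %d; failed replicates: %d\n",
              x$n_penalized_refits, x$n_failed_replicates))
  print(utils::head(x$cells, 8L), row.names = FALSE)
  if (nrow(x$cells) > 8L) cat("  ...\n")
  invisible(x)
}

#' Export a diagnostic grid as delimited text
#'
#' The `"long"` layout writes one row per `(delta, k)` cell with all five
#' metrics and the pooled 2x2 counts. The `"table4"` layout mirrors the
#' conventional presentation: one row per confidence level `k x 100%` and a
#' (sensitivity, specificity) column pair per `delta`.
#'
#' @param grid A `diagnostic_grid`.
#' @param path Output path.
#' @param layout `"long"` or `"table4"`.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
export_grid <- function(grid, path, layout = c("long", "table4"), sep = ",") {
  stopifnot(inherits(grid, "diagnostic_grid"))
  layout <- match.arg(layout)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  if (layout == "long") {
    out <- grid$cells
    for (nm in c("sensitivity", "specificity", "ppv", "npv", "percent_correct",
                 "mc_se_sensitivity", "mc_se_specificity")) {
      out[[nm]] <- fmt(out[[nm]])
    }
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    deltas <- sort(unique(grid$cells$delta))
    ks <- sort(unique(grid$cells$k))
    out <- data.frame(k_percent = ks * 100)
    for (d in deltas) {
      sub <- grid$cells[grid$cells$delta == d, ]
      sub <- sub[match(ks, sub$k), ]
      out[[sprintf("sens_delta_%g", d)]] <- fmt(sub$sensitivity)
      out[[sprintf("spec_delta_%g", d)]] <- fmt(sub$specificity)
    }
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
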