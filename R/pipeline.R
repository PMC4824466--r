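# End-to-end pipeline: generate -> filter -> fit -> standardize ->
# classify -> evaluate -> roc, with a checksum manifest for reproducibility.

pipeline_stages <- c("generate", "filter", "fit", "standardize",
                     "classify", "evaluate", "roc")

#' Pipeline configuration
#'
#' Bundles every choice the pipeline needs: the synthetic-registry
#' generator configuration, the decision-rule settings, the simulation
#' plan, and a root seed. A seed is mandatory — every stochastic stage
#' derives its own stream from it.
#'
#' @param seed Integer root seed (required).
#' @param generator A [generator_config()]; default
#'   [default_config_riksstroke()].
#' @param delta,k Decision-rule settings used by the `classify` stage and
#'   the `roc` stage.
#' @param plan_S,delta_grid,k_grid Simulation-study settings for the
#'   `evaluate` stage.
#' @param stages Which stages to run, in pipeline order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, generator = default_config_riksstroke(),
                            delta = 0.10, k = 0.95, plan_S = 200L,
                            delta_grid = c(0, 0.10, 0.15, 0.20),
                            k_grid = c(0.10, 0.30, 0.50, 0.75, 0.90, 0.95, 0.99),
                            stages = pipeline_stages) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("pipeline_config requires an explicit seed", call. = FALSE)
  }
  stopifnot(inherits(generator, "generator_config"),
            all(stages %in% pipeline_stages))
  structure(list(seed = as.integer(seed), generator = generator,
                 delta = delta, k = k, plan_S = as.integer(plan_S),
                 delta_grid = delta_grid, k_grid = k_grid,
                 stages = stages[order(match(stages, pipeline_stages))]),
            class = "pipeline_config")
}

prepend_header <- function(path, line) {
  txt <- readLines(path)
  writeLines(c(line, txt), path)
  path
}

#' Run the profiling pipeline
#'
#' Executes the selected stages in order, writing every artifact under
#' `out_dir` together with `manifest.json` (seed, configuration checksum,
#' package version, and the MD5 checksum of every artifact). Identical
#' configurations produce byte-identical artifacts and hence identical
#' manifest checksums. Progress is logged to standard error; on stage
#' failure a `FAILED` marker file naming the stage is left in `out_dir` and
#' the error is re-raised.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) {
    message(sprintf("[hospbench] %s", sprintf(...)))
  }
  config_path <- file.path(out_dir, "generator_config.yaml")
  write_generator_config(config$generator, config_path)
  config_checksum <- unname(tools::md5sum(config_path))
  stamp <- sprintf("# config=%s seed=%d", config_checksum, config$seed)
  artifacts <- c(generator_config.yaml = config_path)

  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_msg("stage %-11s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    invisible(ok)
  }
  add_artifact <- function(nm, path, header = TRUE) {
    if (header) prepend_header(path, stamp)
    artifacts[[nm]] <<- path
  }

  run_stage("generate", function() {
    gen <- generate_cohort(config$generator, seed = config$seed)
    state$raw_cohort <- gen$cohort
    state$truth <- gen$truth
    p <- file.path(out_dir, "cohort.csv")
    write_cohort(gen$cohort, p)
    add_artifact("cohort.csv", p)
    pt <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(psi = gen$truth$psi, true_Rh = gen$truth$true_Rh,
           true_population_risk = gen$truth$true_population_risk),
      pt, digits = NA)
    add_artifact("truth.json", pt, header = FALSE)
  })

  run_stage("filter", function() {
    if (is.null(state$raw_cohort)) {
      state$raw_cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
    }
    flt <- apply_inclusion_criteria(state$raw_cohort)
    state$cohort <- flt$cohort
    p <- file.path(out_dir, "exclusion_report.json")
    write_exclusion_report(flt$report, p, format = "json")
    add_artifact("exclusion_report.json", p, header = FALSE)
  })

  run_stage("fit", function() {
    state$design <- encode_design(state$cohort, "reference")
    state$fit <- fit_casemix_model(state$design)
    tab <- coefficient_table(state$fit, design = state$design)
    p <- file.path(out_dir, "coefficients.csv")
    write_coefficient_table(tab, p)
    add_artifact("coefficients.csv", p)
  })

  run_stage("standardize", function() {
    state$risks <- standardized_risks(state$fit, state$design)
    p <- file.path(out_dir, "standardized_risks.csv")
    write_risks(state$risks, p, k = config$k)
    add_artifact("standardized_risks.csv", p)
  })

  run_stage("classify", function() {
    dec <- classify_hospitals(state$risks, delta = config$delta, k = config$k)
    p <- file.path(out_dir, "decisions.csv")
    write_decisions(dec, p)
    add_artifact("decisions.csv", p)
  })

  run_stage("evaluate", function() {
    plan <- simulation_plan(S = config$plan_S, delta_grid = config$delta_grid,
                            k_grid = config$k_grid, seed = config$seed + 1L)
    grid <- run_simulation_study(state$cohort, state$fit, plan)
    state$grid <- grid
    p1 <- file.path(out_dir, "diagnostics_long.csv")
    export_grid(grid, p1, layout = "long")
    add_artifact("diagnostics_long.csv", p1)
    p2 <- file.path(out_dir, "diagnostics_table.csv")
    export_grid(grid, p2, layout = "table4")
    add_artifact("diagnostics_table.csv", p2)
    log_msg("evaluate: %d penalized refits, %d failed replicates",
            grid$n_penalized_refits, grid$n_failed_replicates)
  })

  run_stage("roc", function() {
    input <- planner_input(state$risks, delta = config$delta,
                           k_grid = config$k_grid,
                           population_risk = attr(state$risks, "population_risk"))
    curve <- theoretical_roc(input)
    p <- file.path(out_dir, "roc_planner.csv")
    export_planner(curve, p)
    add_artifact("roc_planner.csv", p)
  })

  manifest <- list(
    package = "hospbench",
    version = as.character(utils::packageVersion("hospbench")),
    seed = config$seed,
    config_checksum = config_checksum,
    stages = config$stages,
    checksums = as.list(vapply(artifacts, function(p) unname(tools::md5sum(p)),
                               character(1)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
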