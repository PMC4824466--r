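# The benchmark decision rule: benchmark construction, hospital
# classification, gold-standard labelling, and 2x2 diagnostic summaries.

#' Benchmark value
#'
#' The maximum tolerated standardized risk: `(1 + delta)` times the
#' observed population risk, where `delta` is the clinically chosen
#' relative excess margin. With `delta = 0.20` and a population risk of
#' 25%, the benchmark is a 30% standardized risk.
#'
#' @param population_risk Observed (crude) population event proportion.
#' @param delta Relative excess margin, `delta >= -1`.
#' @return The benchmark `B` on the risk scale.
#' @export
benchmark_value <- function(population_risk, delta) {
  stopifnot(is.numeric(population_risk), is.numeric(delta))
  if (any(population_risk < 0 | population_risk > 1)) {
    stop("population_risk must lie in [0, 1]", call. = FALSE)
  }
  if (any(delta < -1)) stop("delta must be >= -1", call. = FALSE)
  (1 + delta) * population_risk
}

#' Classify hospitals against a benchmark
#'
#' Labels hospital `h` *outlying* when the `k x 100%` one-sided lower
#' confidence bound of its standardized risk strictly exceeds the benchmark
#' `B = (1 + delta) * population_risk`, and *acceptable* otherwise. A
#' hospital exactly at the benchmark is acceptable. At `k = 0.5` the rule
#' reduces to comparing the point estimate `R_h` to `B`.
#'
#' @param risks A [standardized_risks()] table (needs its
#'   `population_risk` attribute, or pass `population_risk` explicitly).
#' @param delta Relative excess margin.
#' @param k One-sided confidence level in (0, 1).
#' @param population_risk Override for the observed population risk.
#' @return A `decision_set` data frame: `hospital_id`, `lower_bound`,
#'   `outlying` (logical), with attributes `benchmark`, `delta`, `k`.
#' @export
classify_hospitals <- function(risks, delta, k,
                               population_risk = attr(risks, "population_risk")) {
  stopifnot(is.data.frame(risks), all(c("hospital_id", "R", "SE") %in% names(risks)))
  if (is.null(population_risk)) {
    stop("population_risk is required (attribute missing on 'risks')", call. = FALSE)
  }
  if (any(risks$SE <= 0)) stop("standard errors must be positive", call. = FALSE)
  B <- benchmark_value(population_risk, delta)
  lb <- one_sided_lower_bound(risks$R, risks$SE, k)
  out <- data.frame(
    hospital_id = risks$hospital_id,
    lower_bound = lb,
    outlying = lb > B,
    stringsAsFactors = FALSE
  )
  attr(out, "benchmark") <- B
  attr(out, "delta") <- delta
  attr(out, "k") <- k
  class(out) <- c("decision_set", "data.frame")
  out
}

#' Gold-standard excess-risk labels
#'
#' Truth labels for the diagnostic evaluation: hospital `h` has *true
#' excess risk* when its standardized risk from the original (non-
#' resampled) fit strictly exceeds `(1 + delta)` times the original
#' observed population risk.
#'
#' @param risks The original-fit [standardized_risks()] table.
#' @param delta Relative excess margin.
#' @param population_risk Override for the original population risk.
#' @return Named logical vector (`TRUE` = true excess risk).
#' @export
gold_standard_labels <- function(risks, delta,
                                 population_risk = attr(risks, "population_risk")) {
  stopifnot(is.data.frame(risks))
  if (is.null(population_risk)) {
    stop("population_risk is required (attribute missing on 'risks')", call. = FALSE)
  }
  B <- benchmark_value(population_risk, delta)
  stats::setNames(risks$R > B, risks$hospital_id)
}

#' Diagnostic summary of classifications against a gold standard
#'
#' Pools all hospital-by-replicate decisions into one 2x2 table against the
#' fixed per-hospital truth and returns sensitivity, specificity, positive
#' and negative predictive values and the proportion correctly classified.
#' A metric whose denominator class is empty (e.g. sensitivity when no
#' hospital is truly in excess) is reported as `NA` — a distinguished
#' "undefined" marker, never the result of 0/0 arithmetic.
#'
#' @param decisions Logical matrix of flags, one row per replicate and one
#'   column per hospital (a single replicate may be given as a vector).
#' @param truth Logical vector of gold-standard labels, one per hospital.
#' @return A `diagnostic_summary` list: `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `percent_correct`, and `counts` (TP, FP, TN, FN).
#' @export
compute_diagnostics <- function(decisions, truth) {
  if (is.vector(decisions)) decisions <- matrix(decisions, nrow = 1L)
  truth <- as.logical(truth)
  if (ncol(decisions) != length(truth)) {
    stop("decisions and truth are misaligned: ", ncol(decisions),
         " hospitals vs ", length(truth), " truth labels", call. = FALSE)
  }
  S <- nrow(decisions)
  flagged_per_hospital <- colSums(decisions)
  tp <- sum(flagged_per_hospital[truth])
  fn <- S * sum(truth) - tp
  fp <- sum(flagged_per_hospital[!truth])
  tn <- S * sum(!truth) - fp
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    percent_correct = ratio(tp + tn, tp + fp + tn + fn),
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn)
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat("<diagnostic_summary>\n")
  cat(sprintf("  sensitivity %s  specificity %s\n",
              fmt(x$sensitivity), fmt(x$specificity)))
  cat(sprintf("  PPV %s  NPV %s  percent correct %s\n",
              fmt(x$ppv), fmt(x$npv), fmt(x$percent_correct)))
  cat(sprintf("  counts: TP %d FP %d TN %d FN %d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  invisible(x)
}

#' Export a decision set as delimited text
#'
#' @param x A `decision_set` from [classify_hospitals()].
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "decision_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# benchmark=%.17g delta=%g k=%g",
                     attr(x, "benchmark"), attr(x, "delta"), attr(x, "k")), con)
  out <- as.data.frame(x)
  out$lower_bound <- sprintf("%.17g", out$lower_bound)
  out$label <- ifelse(out$outlying, "outlying", "acceptable")
  out$outlying <- NULL
  utils::write.table(out, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
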