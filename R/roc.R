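# Theoretical ROC planner: from hospital standardized risks and standard
# errors plus a margin delta, the flag probability of each hospital under
# the normal sampling model, and the implied sensitivity/specificity
# curves over a grid of confidence levels k.

#' Probability that a hospital is flagged
#'
#' Under the normal approximation — the estimated standardized risk
#' distributed `N(R, SE^2)` — the probability that the `k`-level one-sided
#' lower bound exceeds the benchmark `B` is
#' `P(flag) = pnorm((R - B)/SE - qnorm(k))`. For a hospital exactly at the
#' benchmark this is `1 - k`.
#'
#' @param R True (or last-period) standardized risk(s).
#' @param SE Standard error(s), positive.
#' @param B Benchmark value.
#' @param k One-sided confidence level in (0, 1).
#' @return Flag probability, vectorized over hospitals.
#' @export
flag_probability <- function(R, SE, B, k) {
  if (any(SE <= 0)) stop("SE must be positive", call. = FALSE)
  if (any(k <= 0 | k >= 1)) stop("k must lie strictly in (0, 1)", call. = FALSE)
  stats::pnorm((R - B) / SE - stats::qnorm(k))
}

#' Planner input
#'
#' Bundles the hospital risks and standard errors (e.g. last year's
#' [standardized_risks()] export), the margin `delta` and the `k` grid for
#' the theoretical ROC computation.
#'
#' @param risks Data frame with `hospital_id`, `R`, `SE` (e.g. from
#'   [read_risks()]).
#' @param delta Relative excess margin.
#' @param k_grid Confidence levels to evaluate.
#' @param population_risk Population risk defining the benchmark. When
#'   absent (and not carried as an attribute of `risks`), it defaults to
#'   the **unweighted mean of the supplied `R` values** — a convention, not
#'   an estimate; supply the observed value whenever it is available.
#' @return A `planner_input` list.
#' @export
planner_input <- function(risks, delta,
                          k_grid = seq(0.01, 0.99, by = 0.01),
                          population_risk = NULL) {
  stopifnot(is.data.frame(risks), all(c("hospital_id", "R", "SE") %in% names(risks)))
  if (any(risks$SE <= 0)) stop("SE must be positive", call. = FALSE)
  if (any(risks$R <= 0 | risks$R >= 1)) stop("risks must lie in (0, 1)", call. = FALSE)
  stopifnot(all(k_grid > 0 & k_grid < 1), length(k_grid) >= 1, delta >= -1)
  if (is.null(population_risk)) population_risk <- attr(risks, "population_risk")
  if (is.null(population_risk)) population_risk <- mean(risks$R)
  structure(list(risks = risks, delta = delta, k_grid = sort(k_grid),
                 population_risk = population_risk),
            class = "planner_input")
}

#' Theoretical ROC of the decision rule
#'
#' Treating the supplied `(R, SE)` as the truth, hospitals with `R`
#' strictly above the benchmark `B = (1 + delta) * population_risk` are the
#' true-excess class. The theoretical sensitivity at confidence level `k`
#' is the mean [flag_probability()] over the true-excess hospitals, and the
#' theoretical specificity is the mean non-flag probability over the
#' acceptable hospitals. An empty class yields `NA` for its metric.
#'
#' @param input A [planner_input()].
#' @return A `roc_curve`: data frame `curve` with `k`, `sensitivity`,
#'   `specificity`; matrix `flag_prob` (hospitals by k); the truth labels;
#'   `benchmark`; `delta`.
#' @export
theoretical_roc <- function(input) {
  stopifnot(inherits(input, "planner_input"))
  B <- benchmark_value(input$population_risk, input$delta)
  truth <- input$risks$R > B
  fp <- vapply(input$k_grid, function(k) {
    flag_probability(input$risks$R, input$risks$SE, B, k)
  }, numeric(nrow(input$risks)))
  fp <- matrix(fp, nrow = nrow(input$risks),
               dimnames = list(input$risks$hospital_id,
                               sprintf("k=%g", input$k_grid)))
  sens <- if (any(truth)) colMeans(fp[truth, , drop = FALSE]) else
    rep(NA_real_, length(input$k_grid))
  spec <- if (any(!truth)) colMeans(1 - fp[!truth, , drop = FALSE]) else
    rep(NA_real_, length(input$k_grid))
  structure(list(
    curve = data.frame(k = input$k_grid, sensitivity = unname(sens),
                       specificity = unname(spec)),
    flag_prob = fp,
    truth = stats::setNames(truth, input$risks$hospital_id),
    benchmark = B, delta = input$delta,
    population_risk = input$population_risk
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> delta = %g, benchmark = %.4f, %d hospitals (%d in excess), %d k values\n",
              x$delta, x$benchmark, nrow(x$flag_prob), sum(x$truth),
              nrow(x$curve)))
  invisible(x)
}

#' Export a theoretical ROC curve as delimited text
#'
#' One row per `k`: the theoretical sensitivity and specificity followed by
#' each hospital's flag probability.
#'
#' @param curve A `roc_curve` from [theoretical_roc()].
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
export_planner <- function(curve, path, sep = ",") {
  stopifnot(inherits(curve, "roc_curve"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  out <- curve$curve
  out$sensitivity <- fmt(out$sensitivity)
  out$specificity <- fmt(out$specificity)
  hp <- t(curve$flag_prob)
  colnames(hp) <- paste0("flag_prob_", rownames(curve$flag_prob))
  out <- cbind(out, as.data.frame(apply(hp, 2L, fmt)))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a theoretical ROC curve
#'
#' Base-graphics ROC plot (1 - specificity against sensitivity along the
#' `k` grid), with the `k = 0.5` and `k = 0.95` operating points marked.
#'
#' @param x A `roc_curve`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.roc_curve <- function(x, ...) {
  cv <- x$curve[stats::complete.cases(x$curve), ]
  graphics::plot(1 - cv$specificity, cv$sensitivity, type = "l",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("Theoretical ROC (delta = %g)", x$delta), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  for (k0 in c(0.5, 0.95)) {
    i <- which.min(abs(cv$k - k0))
    graphics::points(1 - cv$specificity[i], cv$sensitivity[i], pch = 19)
    graphics::text(1 - cv$specificity[i], cv$sensitivity[i],
                   sprintf("k=%.2f", cv$k[i]), pos = 4, cex = 0.8)
  }
  invisible(x)
}
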