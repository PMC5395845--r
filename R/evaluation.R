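# Discrimination and case-mix descriptors: rank-based AUC, SD of the linear
# predictor, outcome-stratified predictor summaries.

#' Mann-Whitney (midrank) AUC
#'
#' Concordance probability that a randomly chosen case scores higher than a
#' randomly chosen control, computed from midranks:
#' `(sum of case ranks - n_case(n_case+1)/2) / (n_case * n_control)`, with
#' ties contributing 1/2. Under `direction = "auto"` the returned value is
#' `max(A, 1 - A)` and `flipped` records whether the complement was taken —
#' the convention for transported models whose score may rank inversely to
#' the outcome in the validation population. Under `"fixed"` the raw `A` is
#' returned.
#'
#' @param scores Numeric model scores (linear predictors or risks; any
#'   monotone transform gives the same AUC).
#' @param y 0/1 outcome vector; both classes must be present.
#' @param direction `"fixed"` (default) or `"auto"`.
#' @return List with elements `auc` and `flipped`.
#' @export
#' @examples
#' auc_mann_whitney(c(3, 1, 2, 0), c(1, 0, 1, 0))$auc          # 1
#' auc_mann_whitney(c(1, 2, 0, 3), c(1, 0, 1, 0))$auc          # 0.25
#' auc_mann_whitney(c(1, 2, 0, 3), c(1, 0, 1, 0), "auto")$auc  # 0.75
auc_mann_whitney <- function(scores, y, direction = c("fixed", "auto")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(scores), length(scores) == length(y))
  y <- as.integer(y)
  check_two_classes(y, "AUC input")
  n1 <- sum(y == 1L)
  n0 <- length(y) - n1
  r <- rank(scores) # midranks: ties counted as 1/2
  a <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  flipped <- FALSE
  if (direction == "auto" && a < 0.5) {
    a <- 1 - a
    flipped <- TRUE
  }
  list(auc = a, flipped = flipped)
}

#' Standard deviation of the linear predictor over a cohort
#'
#' The spread of `b0 + b1*x1 + b2*x2` across a population measures case-mix
#' heterogeneity: more heterogeneous populations spread risk scores wider and
#' support higher discrimination. Sample SD with the n-1 denominator.
#'
#' @param model A converged `risk_model`.
#' @param cohort A `cohort` (or bare predictor matrix).
#' @return Non-negative scalar.
#' @export
sd_linear_predictor <- function(model, cohort) {
  stats::sd(linear_predictor(model, cohort))
}

#' Outcome-stratified predictor summaries
#'
#' Sample means, SDs and Pearson correlation of the two predictors within
#' cases and within controls.
#'
#' @param cohort A `cohort` with at least 3 cases and 3 controls.
#' @return List with elements `case` and `control`, each
#'   `list(mu = pair, sigma = pair, rho = scalar)`.
#' @export
group_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  check_two_classes(cohort$y)
  one <- function(keep) {
    if (sum(keep) < 3L) {
      stop("each outcome group needs >= 3 members for a correlation",
           call. = FALSE)
    }
    xg <- cohort$x[keep, , drop = FALSE]
    list(mu = colMeans(xg), sigma = apply(xg, 2L, stats::sd),
         rho = stats::cor(xg[, 1], xg[, 2]))
  }
  list(case = one(cohort$y == 1L), control = one(cohort$y == 0L))
}

#' Evaluate a risk model in a cohort
#'
#' Bundles the package's performance and case-mix descriptors for one
#' (model, cohort) pair: Mann-Whitney AUC of the model's linear predictor
#' against the cohort outcomes, SD of the linear predictor, and per-outcome
#' group predictor summaries.
#'
#' @param model A converged `risk_model`.
#' @param cohort A `cohort`.
#' @param direction AUC direction convention, `"fixed"` for development
#'   (in-sample) evaluation, `"auto"` for transported models; see
#'   [auc_mann_whitney()].
#' @return An `evaluation_report`.
#' @export
evaluate_model <- function(model, cohort, direction = c("fixed", "auto")) {
  direction <- match.arg(direction)
  lp <- linear_predictor(model, cohort)
  a <- auc_mann_whitney(lp, cohort$y, direction)
  gs <- group_summaries(cohort)
  structure(
    list(population_id = cohort$population_id,
         model_population = model$development_population,
         auc = a$auc, auc_direction_flipped = a$flipped,
         sd_lp = stats::sd(lp),
         case_summary = gs$case, control_summary = gs$control,
         n_cases = sum(cohort$y == 1L), n_controls = sum(cohort$y == 0L)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation of model '%s' in population '%s' (%d cases / %d controls)\n",
    x$model_population, x$population_id, x$n_cases, x$n_controls))
  cat(sprintf("  AUC = %.3f%s, SD of linear predictor = %.3f\n", x$auc,
              if (x$auc_direction_flipped) " (direction flipped)" else "",
              x$sd_lp))
  cat(sprintf("  cases:    mu = (%.2f, %.2f), sigma = (%.2f, %.2f), rho = %.2f\n",
              x$case_summary$mu[1], x$case_summary$mu[2],
              x$case_summary$sigma[1], x$case_summary$sigma[2],
              x$case_summary$rho))
  cat(sprintf("  controls: mu = (%.2f, %.2f), sigma = (%.2f, %.2f), rho = %.2f\n",
              x$control_summary$mu[1], x$control_summary$mu[2],
              x$control_summary$sigma[1], x$control_summary$sigma[2],
              x$control_summary$rho))
  invisible(x)
}

# One table row per report, in the layout of the development-summary tables:
# rounding follows the reporting convention (2 decimals, AUC to 3).
report_row <- function(r, digits = 2L, auc_digits = 3L) {
  data.frame(
    population = r$population_id,
    model_population = r$model_population,
    rho_case = round(r$case_summary$rho, digits),
    mu1_case = round(r$case_summary$mu[1], digits),
    mu2_case = round(r$case_summary$mu[2], digits),
    sd1_case = round(r$case_summary$sigma[1], digits),
    sd2_case = round(r$case_summary$sigma[2], digits),
    rho_control = round(r$control_summary$rho, digits),
    mu1_control = round(r$control_summary$mu[1], digits),
    mu2_control = round(r$control_summary$mu[2], digits),
    sd1_control = round(r$control_summary$sigma[1], digits),
    sd2_control = round(r$control_summary$sigma[2], digits),
    sd_lp = round(r$sd_lp, digits),
    auc = round(r$auc, auc_digits),
    flipped = r$auc_direction_flipped,
    stringsAsFactors = FALSE)
}

#' Write evaluation reports as a CSV table
#'
#' One row per (model, cohort) pair, columns mirroring the development
#' summary layout (case and control means/SDs/correlation, SD of the linear
#' predictor, AUC, direction-flip flag). Values are rounded to 2 decimals
#' except the AUC (3).
#'
#' @param reports An `evaluation_report` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(reports, path) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, report_row))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
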