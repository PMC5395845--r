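# Two-predictor logistic risk models: fitting, transport, linear predictors.

new_risk_model <- function(intercept, coefficients, development_population,
                           fit = list()) {
  structure(
    list(intercept = as.double(intercept),
         coefficients = as.double(coefficients),
         development_population = development_population,
         fit = fit),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Logistic risk model (developed in '%s')\n",
              x$development_population))
  cat(sprintf("  intercept %.4f, coefficients (%.4f, %.4f), adjusted ORs (%.3f, %.3f)\n",
              x$intercept, x$coefficients[1], x$coefficients[2],
              exp(x$coefficients[1]), exp(x$coefficients[2])))
  if (length(x$fit)) {
    cat(sprintf("  fit: %d iterations, converged = %s, max |mean score| = %.2e\n",
                x$fit$iterations, x$fit$converged, x$fit$max_score))
  }
  invisible(x)
}

#' Fit a two-predictor logistic regression to a cohort
#'
#' Maximum-likelihood fit of `y ~ x1 + x2` with a logit link, via iteratively
#' reweighted least squares driven to a relative deviance change below 1e-12.
#' The returned model records the development population and fit diagnostics:
#' iteration count, convergence flag, and the largest absolute component of
#' the mean score vector `mean(z * (y - p))` over `z in {1, x1, x2}`, which is
#' ~0 at the optimum.
#'
#' @param cohort A `cohort` with both outcome classes present.
#' @return A `risk_model`.
#' @section Errors: complete or quasi-complete separation (coefficients
#'   diverging past 50 in absolute value, or boundary fitted probabilities)
#'   and non-convergence both raise errors carrying the diagnostics.
#' @export
#' @examples
#' spec <- population_spec_a1("A", rho = 0.2, adjusted_or = c(1.5, 1.5),
#'                            n = 5000)
#' fit_logistic(simulate_population_a1(spec, 1))
fit_logistic <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  check_two_classes(cohort$y)
  if (abs(stats::cor(cohort$x[, 1], cohort$x[, 2])) > 1 - 1e-12) {
    stop("predictors are perfectly collinear; model is not identifiable",
         call. = FALSE)
  }
  df <- data.frame(y = cohort$y, x1 = cohort$x[, 1], x2 = cohort$x[, 2])
  fit <- stats::glm(y ~ x1 + x2, family = stats::binomial(),
                    data = df,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100L))
  cf <- stats::coef(fit)
  p <- stats::fitted(fit)
  score <- colMeans(cbind(1, cohort$x) * (cohort$y - p))
  diag <- list(iterations = fit$iter, converged = fit$converged,
               max_score = max(abs(score)))
  if (any(abs(cf[-1]) > 50) || any(p < 1e-12) || any(p > 1 - 1e-12)) {
    stop(sprintf(
      "separation detected while fitting cohort '%s': coefficients (%.3g, %.3g)",
      cohort$population_id, cf[2], cf[3]), call. = FALSE)
  }
  if (!fit$converged) {
    stop(sprintf(
      "logistic fit did not converge after %d iterations (max |mean score| = %.3g)",
      diag$iterations, diag$max_score), call. = FALSE)
  }
  new_risk_model(cf[[1]], cf[2:3], cohort$population_id, diag)
}

#' Linear predictor of a risk model
#'
#' @param model A converged `risk_model`.
#' @param x An `n x 2` predictor matrix or a `cohort`.
#' @return Numeric vector `b0 + b1*x1 + b2*x2`, one value per row.
#' @export
linear_predictor <- function(model, x) {
  stopifnot(inherits(model, "risk_model"))
  x <- predictor_matrix(x)
  model$intercept + drop(x %*% model$coefficients)
}

#' Predicted risks of a risk model
#'
#' Inverse-logit transform of [linear_predictor()]; all outputs in (0, 1).
#'
#' @inheritParams linear_predictor
#' @return Numeric probability vector.
#' @export
predicted_risk <- function(model, x) {
  stats::plogis(linear_predictor(model, x))
}

#' Write a risk model to JSON
#'
#' Serialized at full double precision so a read back is lossless.
#'
#' @param model A `risk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  rec <- list(intercept = model$intercept,
              coefficients = model$coefficients,
              development_population = model$development_population,
              fit = model$fit)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a risk model from JSON
#'
#' @param path Path written by [write_risk_model()].
#' @return A `risk_model`.
#' @export
read_risk_model <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_risk_model(rec$intercept, rec$coefficients,
                 rec$development_population, as.list(rec$fit))
}
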