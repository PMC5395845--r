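# Approach I: total-population predictor distribution, fixed adjusted ORs,
# intercept calibrated to the target prevalence, Bernoulli outcomes.

# 2x2 covariance from SDs and correlation.
cov2x2 <- function(sigma, rho) {
  matrix(c(sigma[1]^2, rho * sigma[1] * sigma[2],
           rho * sigma[1] * sigma[2], sigma[2]^2), 2L, 2L)
}

# n draws from a bivariate Gaussian via the Cholesky factor of the
# covariance applied to independent standard normals.
rbvnorm <- function(n, mu, sigma, rho) {
  R <- chol(cov2x2(sigma, rho))
  z <- matrix(stats::rnorm(2L * n), n, 2L)
  sweep(z %*% R, 2L, mu, "+")
}

#' Draw correlated Gaussian predictors for a total population
#'
#' Samples `spec$n` i.i.d. rows from the bivariate Gaussian with means
#' `spec$mu`, SDs `spec$sigma` and correlation `spec$rho`.
#'
#' @param spec A [population_spec_a1()] object.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return An `n x 2` numeric matrix with columns `x1`, `x2`.
#' @export
#' @examples
#' x <- draw_predictors_a1(
#'   population_spec_a1("ex", rho = 0.2, adjusted_or = c(1.5, 1.5), n = 1000),
#'   seed = 1)
#' cor(x)[1, 2]
draw_predictors_a1 <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec_a1"))
  x <- with_seed(seed, rbvnorm(spec$n, spec$mu, spec$sigma, spec$rho))
  colnames(x) <- c("x1", "x2")
  x
}

#' Calibrate a logistic intercept to a target mean risk
#'
#' Finds the intercept `b0` for which the mean of
#' `plogis(b0 + x %*% betas)` over the realized sample equals
#' `target_prevalence`. The mean risk is continuous and strictly increasing in
#' `b0`, so the root is unique; it is located by monotone root finding over an
#' auto-expanded bracket and polished with Newton steps to within 1e-10 of the
#' target mean risk.
#'
#' @param x `n x 2` predictor matrix (or a cohort).
#' @param betas Pair of slope coefficients.
#' @param target_prevalence Target mean risk in (0, 1).
#' @return The calibrated intercept (scalar).
#' @export
#' @examples
#' calibrate_intercept(matrix(0, 4, 2), c(0, 0), 0.2) # = qlogis(0.2)
calibrate_intercept <- function(x, betas, target_prevalence) {
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1L ||
      target_prevalence <= 0 || target_prevalence >= 1) {
    stop("`target_prevalence` must lie strictly in (0, 1)", call. = FALSE)
  }
  x <- predictor_matrix(x)
  eta <- drop(x %*% betas)
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target_prevalence
  lo <- stats::qlogis(target_prevalence) - 1
  hi <- stats::qlogis(target_prevalence) + 1
  while (f(lo) > 0) lo <- lo - 2 * (hi - lo)
  while (f(hi) < 0) hi <- hi + 2 * (hi - lo)
  b0 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  # Newton polish: derivative of mean risk in b0 is mean(p(1-p)) > 0.
  for (i in 1:3) {
    p <- stats::plogis(b0 + eta)
    b0 <- b0 - (mean(p) - target_prevalence) / mean(p * (1 - p))
  }
  b0
}

#' Assign Bernoulli outcomes from individual risks
#'
#' @param risks Vector of probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Integer 0/1 vector of the same length.
#' @export
assign_outcomes <- function(risks, seed) {
  if (!is.numeric(risks) || anyNA(risks) || any(risks < 0 | risks > 1)) {
    stop("`risks` must all lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, stats::rbinom(length(risks), 1L, risks))
}

#' Simulate an Approach I population
#'
#' Draws correlated predictors for the whole population, sets the slope
#' coefficients to `log(spec$adjusted_or)`, calibrates the intercept so the
#' mean predicted risk equals `spec$prevalence`, converts linear predictors to
#' risks through the logit link, and draws each individual's outcome from a
#' Bernoulli with that risk. The predictor and outcome stages consume
#' independent sub-seeds derived from `seed` (see [derive_seed()]).
#'
#' @param spec A [population_spec_a1()] object.
#' @param seed Integer master seed for this cohort.
#' @return A `cohort` with attributes `intercept` (the calibrated value) and
#'   `betas` (the fixed slopes) stored as list fields.
#' @export
#' @examples
#' co <- simulate_population_a1(
#'   population_spec_a1("A", rho = 0.2, adjusted_or = c(1.5, 1.5), n = 2000),
#'   seed = 7)
#' co
simulate_population_a1 <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec_a1"))
  x <- draw_predictors_a1(spec, derive_seed(seed, "predictors"))
  betas <- log(spec$adjusted_or)
  b0 <- calibrate_intercept(x, betas, spec$prevalence)
  risks <- stats::plogis(b0 + drop(x %*% betas))
  y <- assign_outcomes(risks, derive_seed(seed, "outcomes"))
  co <- new_cohort(spec$id, x, y, seed)
  co$generating_intercept <- b0
  co$generating_betas <- betas
  co
}

#' Simulate a population from either kind of specification
#'
#' Generic dispatching on the spec class: Approach I specs go through
#' [simulate_population_a1()], Approach II specs through
#' [simulate_population_a2()].
#'
#' @param spec A population spec.
#' @param seed Integer seed.
#' @return A `cohort`.
#' @export
simulate_population <- function(spec, seed) UseMethod("simulate_population")

#' @export
simulate_population.population_spec_a1 <- function(spec, seed) {
  simulate_population_a1(spec, seed)
}

#' @export
simulate_population.population_spec_a2 <- function(spec, seed) {
  simulate_population_a2(spec, seed)
}
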