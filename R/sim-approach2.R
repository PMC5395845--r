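# Approach II: case/control-conditional predictor distributions; the cohort
# is the two strata concatenated and shuffled, with a fixed case count.

#' Simulate an Approach II population
#'
#' Draws exactly `round(n * prevalence)` cases from the case-conditional
#' bivariate Gaussian and the remaining individuals from the
#' control-conditional one, then concatenates and shuffles the rows with a
#' seed-derived permutation. Unlike Approach I, the case count is fixed, not
#' Bernoulli-random.
#'
#' @param spec A [population_spec_a2()] object.
#' @param seed Integer master seed; case draws, control draws and the shuffle
#'   use independent derived sub-seeds.
#' @return A `cohort`.
#' @export
#' @examples
#' spec <- population_spec_a2("A", mu_case = c(1, 2), mu_control = c(0, 0),
#'   sigma_case = c(2, 2), sigma_control = c(2, 2),
#'   rho_case = 0.2, rho_control = 0.2, n = 1000)
#' sum(simulate_population_a2(spec, 1)$y) # exactly 200
simulate_population_a2 <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec_a2"))
  n_case <- as.integer(round(spec$n * spec$prevalence))
  n_ctrl <- spec$n - n_case
  xc <- with_seed(derive_seed(seed, "cases"),
                  rbvnorm(n_case, spec$mu_case, spec$sigma_case,
                          spec$rho_case))
  xt <- with_seed(derive_seed(seed, "controls"),
                  rbvnorm(n_ctrl, spec$mu_control, spec$sigma_control,
                          spec$rho_control))
  x <- rbind(xc, xt)
  y <- c(rep(1L, n_case), rep(0L, n_ctrl))
  perm <- with_seed(derive_seed(seed, "shuffle"), sample.int(spec$n))
  new_cohort(spec$id, x[perm, , drop = FALSE], y[perm], seed)
}

#' Closed-form total-population moments of a case/control mixture
#'
#' For a two-component Gaussian mixture with case fraction `pi`, the
#' total-population moments are, per predictor,
#' \deqn{\mu_t = \pi \mu_c + (1-\pi)\mu_{ct}}
#' \deqn{\sigma_t^2 = \pi \sigma_c^2 + (1-\pi)\sigma_{ct}^2 +
#'   \pi(1-\pi)(\mu_c - \mu_{ct})^2}
#' and the total covariance is the mixture of within-group covariances plus
#' the between-group term
#' \eqn{\pi(1-\pi)(\mu_{1c}-\mu_{1ct})(\mu_{2c}-\mu_{2ct})}.
#'
#' @param spec A [population_spec_a2()] object.
#' @return A `mixture_summary` with fields `mu_total`, `sigma_total`,
#'   `rho_total` and `unadjusted_or` (per-predictor, from [unadjusted_or()]).
#' @export
#' @examples
#' spec <- population_spec_a2("A", mu_case = c(1, 2), mu_control = c(0, 0),
#'   sigma_case = c(2, 2), sigma_control = c(2, 2),
#'   rho_case = 0.2, rho_control = 0.2)
#' mixture_moments(spec)
mixture_moments <- function(spec) {
  stopifnot(inherits(spec, "population_spec_a2"))
  p <- spec$prevalence
  dmu <- spec$mu_case - spec$mu_control
  mu_t <- p * spec$mu_case + (1 - p) * spec$mu_control
  var_t <- p * spec$sigma_case^2 + (1 - p) * spec$sigma_control^2 +
    p * (1 - p) * dmu^2
  cov_t <- p * spec$rho_case * spec$sigma_case[1] * spec$sigma_case[2] +
    (1 - p) * spec$rho_control * spec$sigma_control[1] * spec$sigma_control[2] +
    p * (1 - p) * dmu[1] * dmu[2]
  out <- list(
    mu_total = mu_t,
    sigma_total = sqrt(var_t),
    rho_total = cov_t / sqrt(var_t[1] * var_t[2]),
    unadjusted_or = c(suppressWarnings(unadjusted_or(spec, 1L)),
                      suppressWarnings(unadjusted_or(spec, 2L))))
  class(out) <- "mixture_summary"
  out
}

#' @export
print.mixture_summary <- function(x, ...) {
  cat(sprintf(
    "Mixture totals: mu = (%.4g, %.4g), sigma = (%.4g, %.4g), rho = %.4g\n",
    x$mu_total[1], x$mu_total[2], x$sigma_total[1], x$sigma_total[2],
    x$rho_total))
  cat(sprintf("  unadjusted ORs: (%.4g, %.4g)\n",
              x$unadjusted_or[1], x$unadjusted_or[2]))
  invisible(x)
}

#' Closed-form unadjusted odds ratio for one predictor
#'
#' For a predictor that is Gaussian in both cases and controls with a common
#' within-group SD, the per-unit unadjusted odds ratio is
#' `exp((mu_case - mu_control) / SD^2)`. When the case and control SDs differ
#' the common-variance condition is violated: the control-group SD is used and
#' a warning is emitted.
#'
#' @param spec A [population_spec_a2()] object.
#' @param component Which predictor, 1 or 2.
#' @return Positive scalar odds ratio.
#' @export
#' @examples
#' spec <- population_spec_a2("I", mu_case = c(1, 2), mu_control = c(0, 0),
#'   sigma_case = c(2, 1), sigma_control = c(2, 1),
#'   rho_case = 0.2, rho_control = 0.2)
#' unadjusted_or(spec, 2) # exp(2)
unadjusted_or <- function(spec, component) {
  stopifnot(inherits(spec, "population_spec_a2"),
            component %in% c(1L, 2L))
  sd_c <- spec$sigma_case[component]
  sd_t <- spec$sigma_control[component]
  if (sd_c != sd_t) {
    warning(sprintf(
      paste0("case SD (%g) and control SD (%g) differ for predictor %d; ",
             "the closed form assumes a common within-group variance - ",
             "using the control SD"),
      sd_c, sd_t, component), call. = FALSE)
  }
  exp((spec$mu_case[component] - spec$mu_control[component]) / sd_t^2)
}
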