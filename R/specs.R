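# Population specifications for the two simulation approaches.

check_pair <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x)) {
    stop(sprintf("`%s` must be a numeric pair, got: %s", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.double(x)
}

check_rho <- function(rho, name) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) >= 1) {
    stop(sprintf(
      "`%s` must satisfy |rho| < 1 (2x2 predictor covariance must be positive definite), got %s",
      name, format(rho)), call. = FALSE)
  }
  as.double(rho)
}

check_sigma <- function(sigma, name) {
  sigma <- check_pair(sigma, name)
  if (any(sigma <= 0)) {
    stop(sprintf(
      "`%s` components must be > 0 (covariance must be positive definite), got: %s",
      name, paste(format(sigma), collapse = ", ")), call. = FALSE)
  }
  sigma
}

#' Specify a total-population simulation (Approach I)
#'
#' Describes a hypothetical population by the joint distribution of two
#' Gaussian predictors in the *whole* population, together with fixed per-unit
#' adjusted odds ratios. Disease risk follows a logistic model whose slope
#' coefficients are `log(adjusted_or)` and whose intercept is later calibrated
#' so the mean simulated risk equals `prevalence`; outcomes are Bernoulli
#' draws from those risks.
#'
#' @param id Short population label (e.g. `"A"`).
#' @param rho Pearson correlation of the two predictors in the total
#'   population, in (-1, 1).
#' @param adjusted_or Pair of positive per-unit odds ratios, fixed a priori.
#' @param mu Pair of predictor means (default `c(0, 0)`).
#' @param sigma Pair of positive predictor standard deviations (default
#'   `c(1, 1)`).
#' @param n Number of individuals (default 100000).
#' @param prevalence Target mean disease risk in (0, 1) (default 0.2).
#' @return An object of class `population_spec_a1`.
#' @seealso [simulate_population()], [table1_specs()]
#' @export
#' @examples
#' population_spec_a1("A", rho = 0.2, adjusted_or = c(1.5, 1.5))
population_spec_a1 <- function(id, rho, adjusted_or, mu = c(0, 0),
                               sigma = c(1, 1), n = 1e5, prevalence = 0.2) {
  stopifnot(is.character(id) || is.factor(id), length(id) == 1L)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly in (0, 1)", call. = FALSE)
  }
  adjusted_or <- check_pair(adjusted_or, "adjusted_or")
  if (any(adjusted_or <= 0)) stop("`adjusted_or` must be positive", call. = FALSE)
  spec <- list(
    id = as.character(id), n = n, prevalence = as.double(prevalence),
    mu = check_pair(mu, "mu"), sigma = check_sigma(sigma, "sigma"),
    rho = check_rho(rho, "rho"), adjusted_or = adjusted_or)
  class(spec) <- c("population_spec_a1", "population_spec")
  spec
}

#' Specify a case/control-conditional simulation (Approach II)
#'
#' Describes a hypothetical population by the bivariate-Gaussian distribution
#' of two predictors *within cases* and *within controls*. Exactly
#' `round(n * prevalence)` cases are drawn from the case distribution and the
#' remainder from the control distribution; adjusted predictor effects are not
#' fixed a priori but emerge when a logistic model is fitted to the combined
#' cohort.
#'
#' @param id Short population label.
#' @param mu_case,mu_control Pairs of predictor means per outcome group.
#' @param sigma_case,sigma_control Pairs of positive predictor SDs per group.
#' @param rho_case,rho_control Within-group predictor correlations in (-1, 1).
#' @param n Number of individuals (default 100000).
#' @param prevalence Proportion of cases in (0, 1) (default 0.2).
#' @return An object of class `population_spec_a2`.
#' @seealso [simulate_population()], [mixture_moments()], [table2_specs()]
#' @export
#' @examples
#' population_spec_a2("A",
#'   mu_case = c(1, 2), mu_control = c(0, 0),
#'   sigma_case = c(2, 2), sigma_control = c(2, 2),
#'   rho_case = 0.2, rho_control = 0.2)
population_spec_a2 <- function(id, mu_case, mu_control, sigma_case,
                               sigma_control, rho_case, rho_control,
                               n = 1e5, prevalence = 0.2) {
  stopifnot(is.character(id) || is.factor(id), length(id) == 1L)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (round(n * prevalence) < 1 || round(n * (1 - prevalence)) < 1) {
    stop("`n` and `prevalence` must yield at least one case and one control",
         call. = FALSE)
  }
  spec <- list(
    id = as.character(id), n = n, prevalence = as.double(prevalence),
    mu_case = check_pair(mu_case, "mu_case"),
    mu_control = check_pair(mu_control, "mu_control"),
    sigma_case = check_sigma(sigma_case, "sigma_case"),
    sigma_control = check_sigma(sigma_control, "sigma_control"),
    rho_case = check_rho(rho_case, "rho_case"),
    rho_control = check_rho(rho_control, "rho_control"))
  class(spec) <- c("population_spec_a2", "population_spec")
  spec
}

#' @export
print.population_spec_a1 <- function(x, ...) {
  cat(sprintf(
    "Approach I population spec '%s': n = %d, prevalence = %.3g\n", x$id,
    x$n, x$prevalence))
  cat(sprintf("  predictors ~ N(mu = (%g, %g), sigma = (%g, %g)), rho = %g\n",
              x$mu[1], x$mu[2], x$sigma[1], x$sigma[2], x$rho))
  cat(sprintf("  fixed adjusted ORs: (%g, %g)\n",
              x$adjusted_or[1], x$adjusted_or[2]))
  invisible(x)
}

#' @export
print.population_spec_a2 <- function(x, ...) {
  cat(sprintf(
    "Approach II population spec '%s': n = %d, prevalence = %.3g\n", x$id,
    x$n, x$prevalence))
  cat(sprintf("  cases:    N(mu = (%g, %g), sigma = (%g, %g)), rho = %g\n",
              x$mu_case[1], x$mu_case[2], x$sigma_case[1], x$sigma_case[2],
              x$rho_case))
  cat(sprintf("  controls: N(mu = (%g, %g), sigma = (%g, %g)), rho = %g\n",
              x$mu_control[1], x$mu_control[2], x$sigma_control[1],
              x$sigma_control[2], x$rho_control))
  invisible(x)
}

spec_from_record <- function(rec) {
  if (is.null(rec$approach)) stop("spec record lacks an `approach` field",
                                  call. = FALSE)
  if (rec$approach == 1) {
    population_spec_a1(rec$id, rho = rec$rho, adjusted_or = unlist(rec$adjusted_or),
                       mu = unlist(rec$mu), sigma = unlist(rec$sigma),
                       n = rec$n, prevalence = rec$prevalence)
  } else if (rec$approach == 2) {
    population_spec_a2(rec$id,
                       mu_case = unlist(rec$case$mu),
                       mu_control = unlist(rec$control$mu),
                       sigma_case = unlist(rec$case$sigma),
                       sigma_control = unlist(rec$control$sigma),
                       rho_case = rec$case$rho, rho_control = rec$control$rho,
                       n = rec$n, prevalence = rec$prevalence)
  } else {
    stop("`approach` must be 1 or 2", call. = FALSE)
  }
}

#' Read population specifications from a JSON file
#'
#' The file holds either a single spec object or an array of them. Approach I
#' records carry `{"id", "approach": 1, "n", "prevalence", "mu", "sigma",
#' "rho", "adjusted_or"}`; Approach II records carry `{"id", "approach": 2,
#' "n", "prevalence", "case": {"mu","sigma","rho"}, "control": {...}}`.
#'
#' @param path Path to a JSON spec file.
#' @return A named list of `population_spec_a1` / `population_spec_a2`
#'   objects (named by id), or a single spec if the file holds one object.
#' @seealso [write_population_specs()]
#' @export
read_population_specs <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(recs$id)) return(spec_from_record(recs))
  specs <- lapply(recs, spec_from_record)
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  specs
}

spec_to_record <- function(spec) {
  if (inherits(spec, "population_spec_a1")) {
    list(id = spec$id, approach = 1L, n = spec$n, prevalence = spec$prevalence,
         mu = spec$mu, sigma = spec$sigma, rho = spec$rho,
         adjusted_or = spec$adjusted_or)
  } else {
    list(id = spec$id, approach = 2L, n = spec$n, prevalence = spec$prevalence,
         case = list(mu = spec$mu_case, sigma = spec$sigma_case,
                     rho = spec$rho_case),
         control = list(mu = spec$mu_control, sigma = spec$sigma_control,
                        rho = spec$rho_control))
  }
}

#' Write population specifications to a JSON file
#'
#' @param specs A single population spec or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_population_specs()]
#' @export
write_population_specs <- function(specs, path) {
  recs <- if (inherits(specs, "population_spec")) {
    spec_to_record(specs)
  } else {
    lapply(unname(specs), spec_to_record)
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Bundled Approach I population specifications
#'
#' The sixteen total-population scenarios A-P used throughout the package's
#' worked examples: means fixed at (0, 0), SDs (1, 1) (raised to (1, 3) for
#' M-P), correlations between -0.2 and 0.4, and adjusted odds-ratio pairs
#' covering same-direction, opposite-direction, weak and strong effects.
#' Every population uses n = 100000 and 20% prevalence.
#'
#' @param n Override the per-population size (all sixteen share it); useful
#'   for fast exploratory runs.
#' @return Named list of sixteen [population_spec_a1()] objects.
#' @export
#' @examples
#' names(table1_specs())
table1_specs <- function(n = 1e5) {
  specs <- read_population_specs(
    system.file("extdata", "populations_approach1.json", package = "aucmix",
                mustWork = TRUE))
  lapply(specs, function(s) { s$n <- as.integer(n); s })
}

#' Bundled Approach II population specifications
#'
#' The nine case/control-conditional scenarios A-I: case means (1, 2) to
#' (1, 3) against control means (0, 0) or (0, 2), within-group SDs of 1-3,
#' and within-group correlations between -0.2 and 0.4. Every population uses
#' n = 100000 and 20% cases.
#'
#' @param n Override the per-population size.
#' @return Named list of nine [population_spec_a2()] objects.
#' @export
#' @examples
#' names(table2_specs())
table2_specs <- function(n = 1e5) {
  specs <- read_population_specs(
    system.file("extdata", "populations_approach2.json", package = "aucmix",
                mustWork = TRUE))
  lapply(specs, function(s) { s$n <- as.integer(n); s })
}
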