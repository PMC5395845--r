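# Experiment orchestration: develop a model in every population, validate
# every model in every population, and sweep correlations to trace AUC curves.

#' Develop a risk model in every population
#'
#' For each spec: derive a per-population seed from the master seed and the
#' population id, simulate the cohort, fit the two-predictor logistic model,
#' and evaluate it in-sample (direction `"fixed"`).
#'
#' @param specs List of population specs (Approach I and/or II) with unique
#'   ids.
#' @param master_seed Integer master seed.
#' @return List with named elements `cohorts`, `models`, `reports`, each
#'   itself a list named by population id.
#' @export
#' @examples
#' dev <- develop_all(table1_specs(n = 2000)[c("A", "E")], master_seed = 1)
#' dev$reports$A$auc
develop_all <- function(specs, master_seed) {
  if (length(specs) == 0L) {
    return(list(cohorts = list(), models = list(), reports = list()))
  }
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("population ids must be unique", call. = FALSE)
  cohorts <- models <- reports <- stats::setNames(vector("list", length(ids)),
                                                  ids)
  for (i in seq_along(specs)) {
    co <- simulate_population(specs[[i]], derive_seed(master_seed, ids[i]))
    m <- fit_logistic(co)
    cohorts[[i]] <- co
    models[[i]] <- m
    reports[[i]] <- evaluate_model(m, co, direction = "fixed")
  }
  list(cohorts = cohorts, models = models, reports = reports)
}

#' Cross-validate every model in every population
#'
#' Transports each fitted model unchanged (no recalibration or refitting)
#' into every cohort and records the Mann-Whitney AUC with direction
#' `"auto"`, flagging any orientation flips. Rows are validation populations,
#' columns development populations, so entry `(v, d)` is the AUC of the model
#' developed in `d` when validated in `v`; the diagonal reproduces the
#' development AUCs.
#'
#' @param models Named list of `risk_model`s.
#' @param cohorts Named list of `cohort`s covering the same ids.
#' @return A `validation_matrix`: list with `population_ids`, `auc` (square
#'   matrix) and `flipped` (logical matrix).
#' @export
cross_validate <- function(models, cohorts) {
  ids <- names(models)
  if (is.null(ids) || !setequal(ids, names(cohorts))) {
    stop("`models` and `cohorts` must be named by the same population ids",
         call. = FALSE)
  }
  cohorts <- cohorts[ids]
  k <- length(ids)
  auc <- matrix(NA_real_, k, k, dimnames = list(validated = ids,
                                                developed = ids))
  flipped <- matrix(FALSE, k, k, dimnames = dimnames(auc))
  for (v in seq_len(k)) {
    co <- cohorts[[v]]
    for (d in seq_len(k)) {
      lp <- linear_predictor(models[[d]], co)
      a <- auc_mann_whitney(lp, co$y, direction = "auto")
      auc[v, d] <- a$auc
      flipped[v, d] <- a$flipped
    }
  }
  structure(list(population_ids = ids, auc = auc, flipped = flipped),
            class = "validation_matrix")
}

#' @export
print.validation_matrix <- function(x, digits = 3L, ...) {
  cat(sprintf(
    "Validation matrix (%d populations; rows validated-in, columns developed-in)\n",
    length(x$population_ids)))
  print(round(x$auc, digits))
  if (any(x$flipped)) {
    idx <- which(x$flipped, arr.ind = TRUE)
    cat("direction flipped for (validated, developed):",
        paste(sprintf("(%s, %s)", x$population_ids[idx[, 1]],
                      x$population_ids[idx[, 2]]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a validation matrix as CSV
#'
#' AUCs rounded to 3 decimals, with a leading column of validation-population
#' ids and a header row of development-population ids.
#'
#' @param vm A `validation_matrix`.
#' @param path Output CSV path.
#' @param what `"auc"` (default) or `"flipped"`.
#' @return `path`, invisibly.
#' @export
write_validation_matrix <- function(vm, path, what = c("auc", "flipped")) {
  what <- match.arg(what)
  m <- if (what == "auc") round(vm$auc, 3L) else vm$flipped
  tab <- data.frame(validated_in = vm$population_ids, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

new_sweep_result <- function(grid, auc, sd_lp, scenario,
                             flipped = rep(FALSE, length(grid))) {
  structure(list(grid = grid, auc = auc, sd_lp = sd_lp,
                 scenario = scenario, flipped = flipped),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Correlation sweep [%s]: %d grid points in [%g, %g]\n",
              x$scenario, length(x$grid), min(x$grid), max(x$grid)))
  print(data.frame(rho = x$grid, auc = round(x$auc, 3),
                   sd_lp = round(x$sd_lp, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(scenario = x$scenario, rho = x$grid, auc = x$auc,
             sd_lp = x$sd_lp, stringsAsFactors = FALSE)
}

#' Sweep the total-population correlation (Approach I)
#'
#' For each correlation on the grid: simulate a fresh Approach I population
#' with that correlation (all other parameters from `base`), fit the logistic
#' model, and record the development AUC and the SD of the linear predictor.
#' `or_mode = "same"` fixes the adjusted ORs at (1.5, 1.5) — both effects in
#' the same direction — and `"opposite"` at (1.5, 0.8).
#'
#' @param base A [population_spec_a1()] giving means, SDs, n and prevalence.
#' @param rho_grid Strictly increasing vector of correlations in (-1, 1).
#' @param or_mode `"same"` or `"opposite"`.
#' @param seed Integer master seed; each grid point derives its own sub-seed.
#' @return A `sweep_result`.
#' @export
#' @examples
#' base <- population_spec_a1("base", rho = 0, adjusted_or = c(1.5, 1.5),
#'                            n = 2000)
#' correlation_sweep_a1(base, c(-0.2, 0, 0.2), "same", seed = 1)
correlation_sweep_a1 <- function(base, rho_grid,
                                 or_mode = c("same", "opposite"), seed) {
  stopifnot(inherits(base, "population_spec_a1"))
  or_mode <- match.arg(or_mode)
  if (is.unsorted(rho_grid, strictly = TRUE)) {
    stop("`rho_grid` must be strictly increasing", call. = FALSE)
  }
  ors <- if (or_mode == "same") c(1.5, 1.5) else c(1.5, 0.8)
  auc <- sd_lp <- numeric(length(rho_grid))
  for (i in seq_along(rho_grid)) {
    spec <- population_spec_a1(
      sprintf("%s_rho%+.3f", base$id, rho_grid[i]), rho = rho_grid[i],
      adjusted_or = ors, mu = base$mu, sigma = base$sigma, n = base$n,
      prevalence = base$prevalence)
    co <- simulate_population_a1(spec,
                                 derive_seed(seed, or_mode,
                                             sprintf("%.6f", rho_grid[i])))
    m <- fit_logistic(co)
    lp <- linear_predictor(m, co)
    auc[i] <- auc_mann_whitney(lp, co$y, "fixed")$auc
    sd_lp[i] <- stats::sd(lp)
  }
  new_sweep_result(rho_grid, auc, sd_lp,
                   sprintf("approach I, ORs (%g, %g)", ors[1], ors[2]))
}

#' Sweep case/control correlations (Approach II)
#'
#' One AUC curve per fixed case-correlation level: for each level, the
#' control correlation runs over `rho_control_grid`, a fresh population is
#' simulated per grid point, a model fitted, and the development AUC and SD
#' of the linear predictor recorded. Means and SDs come from `base`.
#'
#' @param base A [population_spec_a2()] giving the group means/SDs, n and
#'   prevalence.
#' @param rho_case_levels Vector of fixed case correlations.
#' @param rho_control_grid Strictly increasing vector of control
#'   correlations.
#' @param seed Integer master seed.
#' @return Named list of `sweep_result`s, one per case-correlation level.
#' @seealso [fig_scenarios_a2()] for the four standard scenario geometries.
#' @export
correlation_sweep_a2 <- function(base, rho_case_levels, rho_control_grid,
                                 seed) {
  stopifnot(inherits(base, "population_spec_a2"))
  if (is.unsorted(rho_control_grid, strictly = TRUE)) {
    stop("`rho_control_grid` must be strictly increasing", call. = FALSE)
  }
  out <- list()
  for (rc in rho_case_levels) {
    auc <- sd_lp <- numeric(length(rho_control_grid))
    for (i in seq_along(rho_control_grid)) {
      spec <- population_spec_a2(
        sprintf("%s_case%+.3f_ctrl%+.3f", base$id, rc, rho_control_grid[i]),
        mu_case = base$mu_case, mu_control = base$mu_control,
        sigma_case = base$sigma_case, sigma_control = base$sigma_control,
        rho_case = rc, rho_control = rho_control_grid[i],
        n = base$n, prevalence = base$prevalence)
      co <- simulate_population_a2(
        spec, derive_seed(seed, sprintf("%.6f", rc),
                          sprintf("%.6f", rho_control_grid[i])))
      m <- fit_logistic(co)
      lp <- linear_predictor(m, co)
      auc[i] <- auc_mann_whitney(lp, co$y, "fixed")$auc
      sd_lp[i] <- stats::sd(lp)
    }
    out[[sprintf("rho_case=%g", rc)]] <- new_sweep_result(
      rho_control_grid, auc, sd_lp,
      sprintf("approach II (%s), rho_case = %g", base$id, rc))
  }
  out
}

#' Standard Approach II sweep scenario geometries
#'
#' The four case/control mean-and-SD layouts used for the correlation-sweep
#' curves: (a) case means (1, 2), control means (0, 0), all SDs 2;
#' (b) larger mean separation for predictor 2 (case means (1, 3));
#' (c) predictor 2 SD raised to 3 in both groups;
#' (d) predictor 2 SD lowered to 1 in both groups.
#'
#' @param n Population size per simulated grid point.
#' @param prevalence Proportion of cases.
#' @return Named list (`a`-`d`) of [population_spec_a2()] base specs (the
#'   correlations are placeholders overridden by the sweep).
#' @export
fig_scenarios_a2 <- function(n = 1e5, prevalence = 0.2) {
  mk <- function(id, mu_case, mu_control, sigma) {
    population_spec_a2(id, mu_case = mu_case, mu_control = mu_control,
                       sigma_case = sigma, sigma_control = sigma,
                       rho_case = 0, rho_control = 0, n = n,
                       prevalence = prevalence)
  }
  list(a = mk("a", c(1, 2), c(0, 0), c(2, 2)),
       b = mk("b", c(1, 3), c(0, 0), c(2, 2)),
       c = mk("c", c(1, 2), c(0, 0), c(2, 3)),
       d = mk("d", c(1, 2), c(0, 0), c(2, 1)))
}

#' Regenerate the package's summary tables and sweep curves as CSV
#'
#' Runs the full study: develops a model in each of the sixteen Approach I
#' and nine Approach II populations, writes the two development-summary
#' tables (`table_approach1.csv`, `table_approach2.csv`, layout of
#' [write_evaluation_csv()]), both cross-validation AUC matrices
#' (`crossval_approach1.csv`, `crossval_approach2.csv` plus `*_flipped.csv`),
#' the two Approach I correlation-sweep curves
#' (`sweep_a1_same.csv`, `sweep_a1_opposite.csv`) and the four Approach II
#' sweep scenarios (`sweep_a2_<scenario>.csv`).
#'
#' @param outdir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param n Population size used everywhere (default 100000).
#' @param rho_grid_a1 Grid for the Approach I sweeps.
#' @param rho_case_levels,rho_control_grid Grids for the Approach II sweeps.
#' @return Invisibly, a list with the in-memory results (`dev1`, `dev2`,
#'   `cv1`, `cv2`, `sweep_a1`, `sweep_a2`).
#' @export
reproduce_tables <- function(outdir, seed = 1L, n = 1e5,
                             rho_grid_a1 = seq(-0.4, 0.4, by = 0.1),
                             rho_case_levels = c(-0.4, -0.2, 0, 0.2, 0.4),
                             rho_control_grid = seq(-0.95, 0.95, by = 0.05)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  dev1 <- develop_all(table1_specs(n = n), derive_seed(seed, "table1"))
  write_evaluation_csv(dev1$reports, p("table_approach1.csv"))
  cv1 <- cross_validate(dev1$models, dev1$cohorts)
  write_validation_matrix(cv1, p("crossval_approach1.csv"))
  write_validation_matrix(cv1, p("crossval_approach1_flipped.csv"),
                          what = "flipped")

  dev2 <- develop_all(table2_specs(n = n), derive_seed(seed, "table2"))
  write_evaluation_csv(dev2$reports, p("table_approach2.csv"))
  cv2 <- cross_validate(dev2$models, dev2$cohorts)
  write_validation_matrix(cv2, p("crossval_approach2.csv"))
  write_validation_matrix(cv2, p("crossval_approach2_flipped.csv"),
                          what = "flipped")

  base1 <- population_spec_a1("sweep", rho = 0, adjusted_or = c(1.5, 1.5),
                              n = n)
  sweep_a1 <- list(
    same = correlation_sweep_a1(base1, rho_grid_a1, "same",
                                derive_seed(seed, "fig1")),
    opposite = correlation_sweep_a1(base1, rho_grid_a1, "opposite",
                                    derive_seed(seed, "fig1")))
  utils::write.csv(as.data.frame(sweep_a1$same), p("sweep_a1_same.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sweep_a1$opposite),
                   p("sweep_a1_opposite.csv"), row.names = FALSE)

  sweep_a2 <- list()
  scen <- fig_scenarios_a2(n = n)
  for (nm in names(scen)) {
    curves <- correlation_sweep_a2(scen[[nm]], rho_case_levels,
                                   rho_control_grid,
                                   derive_seed(seed, "fig3", nm))
    sweep_a2[[nm]] <- curves
    tab <- do.call(rbind, lapply(names(curves), function(k) {
      cbind(rho_case = sub("rho_case=", "", k),
            as.data.frame(curves[[k]]))
    }))
    utils::write.csv(tab, p(sprintf("sweep_a2_%s.csv", nm)),
                     row.names = FALSE)
  }

  invisible(list(dev1 = dev1, dev2 = dev2, cv1 = cv1, cv2 = cv2,
                 sweep_a1 = sweep_a1, sweep_a2 = sweep_a2))
}
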