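# Orchestration: per-population development, cross-validation, sweeps.

test_that("develop_all handles empty input and enforces unique ids", {
  out <- develop_all(list(), 1)
  expect_identical(out, list(cohorts = list(), models = list(),
                             reports = list()))
  specs <- list(a1_spec(id = "X", n = 500), a1_spec(id = "X", n = 500))
  expect_error(develop_all(specs, 1), "unique")
})

test_that("develop_all is deterministic in the master seed and spans approaches", {
  specs <- list(a1_spec(id = "X", n = 4000), a2_spec(id = "Y", n = 4000))
  d1 <- develop_all(specs, 7)
  d2 <- develop_all(specs, 7)
  expect_identical(names(d1$models), c("X", "Y"))
  expect_identical(d1$models$X$coefficients, d2$models$X$coefficients)
  expect_identical(d1$cohorts$Y$x, d2$cohorts$Y$x)
  d3 <- develop_all(specs, 8)
  expect_false(identical(d1$models$X$coefficients, d3$models$X$coefficients))
  expect_s3_class(d1$reports$Y, "evaluation_report")
})

test_that("cross-validation produces a complete, diagonal-consistent matrix", {
  specs <- list(a1_spec(id = "X", rho = 0.2, n = 2e4),
                a1_spec(id = "Y", rho = -0.2, n = 2e4),
                a1_spec(id = "Z", or = c(1.5, 0.8), n = 2e4))
  dev <- develop_all(specs, 3)
  vm <- cross_validate(dev$models, dev$cohorts)
  expect_identical(dim(vm$auc), c(3L, 3L))
  expect_false(any(is.na(vm$auc)))
  for (id in vm$population_ids) {
    expect_equal(vm$auc[id, id], dev$reports[[id]]$auc)
  }
  expect_error(cross_validate(dev$models[1:2], dev$cohorts), "same population ids")
})

test_that("exchangeable populations validate each other like themselves", {
  specs <- list(a1_spec(id = "X", n = 5e4), a1_spec(id = "Y", n = 5e4))
  dev <- develop_all(specs, 11)
  vm <- cross_validate(dev$models, dev$cohorts)
  expect_lt(abs(vm$auc["X", "Y"] - vm$auc["X", "X"]), 0.01)
  expect_lt(abs(vm$auc["Y", "X"] - vm$auc["Y", "Y"]), 0.01)
})

test_that("transported AUC depends only on the coefficient direction", {
  co <- simulate_population_a1(a1_spec(n = 5000), seed = 13)
  m <- fit_logistic(co)
  for (k in c(0.1, 2, 57)) {
    scaled <- aucmix:::new_risk_model(-3, k * m$coefficients, "scaled")
    expect_identical(
      auc_mann_whitney(linear_predictor(scaled, co), co$y, "auto")$auc,
      auc_mann_whitney(linear_predictor(m, co), co$y, "auto")$auc)
  }
})

test_that("a transported model ranking inversely is flagged as flipped", {
  specs <- list(a1_spec(id = "pos", or = c(1.5, 3), n = 2e4),
                a1_spec(id = "neg", or = c(0.8, 0.8), n = 2e4))
  dev <- develop_all(specs, 17)
  vm <- cross_validate(dev$models, dev$cohorts)
  expect_true(vm$flipped["neg", "pos"])
  expect_gte(vm$auc["neg", "pos"], 0.5)
  expect_false(vm$flipped["pos", "pos"])
})

test_that("Approach I sweeps record one AUC/sd_lp pair per grid point", {
  base <- a1_spec(id = "base", n = 3000)
  sw <- correlation_sweep_a1(base, c(-0.2, 0, 0.2), "same", seed = 5)
  expect_s3_class(sw, "sweep_result")
  expect_identical(sw$grid, c(-0.2, 0, 0.2))
  expect_length(sw$auc, 3)
  expect_length(sw$sd_lp, 3)
  expect_true(all(sw$auc > 0 & sw$auc < 1))
  expect_error(correlation_sweep_a1(base, c(0.2, 0.1), "same", 5),
               "strictly increasing")
  df <- as.data.frame(sw)
  expect_identical(names(df), c("scenario", "rho", "auc", "sd_lp"))
})

test_that("Approach II sweeps give one curve per case-correlation level", {
  base <- a2_spec(id = "base", n = 3000)
  curves <- correlation_sweep_a2(base, c(-0.2, 0.2), c(-0.3, 0, 0.3),
                                 seed = 6)
  expect_named(curves, c("rho_case=-0.2", "rho_case=0.2"))
  expect_identical(curves[[1]]$grid, c(-0.3, 0, 0.3))
  single <- correlation_sweep_a2(base, 0.1, 0.25, seed = 6)
  expect_length(single[[1]]$grid, 1)
  expect_length(single[[1]]$auc, 1)
})

test_that("the four standard sweep scenarios carry the documented geometry", {
  sc <- fig_scenarios_a2(n = 1000)
  expect_named(sc, c("a", "b", "c", "d"))
  expect_equal(sc$a$mu_case, c(1, 2))
  expect_equal(sc$b$mu_case, c(1, 3))
  expect_equal(sc$c$sigma_case, c(2, 3))
  expect_equal(sc$d$sigma_case, c(2, 1))
  expect_equal(sc$d$sigma_control, c(2, 1))
})

test_that("reproduce_tables writes the full CSV bundle", {
  outdir <- withr::local_tempdir()
  res <- reproduce_tables(outdir, seed = 2, n = 1500,
                          rho_grid_a1 = c(-0.2, 0.2),
                          rho_case_levels = 0.2,
                          rho_control_grid = c(-0.2, 0.2))
  files <- c("table_approach1.csv", "table_approach2.csv",
             "crossval_approach1.csv", "crossval_approach2.csv",
             "crossval_approach1_flipped.csv", "crossval_approach2_flipped.csv",
             "sweep_a1_same.csv", "sweep_a1_opposite.csv",
             paste0("sweep_a2_", c("a", "b", "c", "d"), ".csv"))
  for (f in files) expect_true(file.exists(file.path(outdir, f)))
  t1 <- read.csv(file.path(outdir, "table_approach1.csv"))
  expect_identical(nrow(t1), 16L)
  cv <- read.csv(file.path(outdir, "crossval_approach2.csv"),
                 check.names = FALSE)
  expect_identical(dim(cv), c(9L, 10L))
  expect_identical(cv$validated_in, names(table2_specs()))
})

test_that("more negative case correlation raises the Approach II AUC", {
  base <- fig_scenarios_a2()$a # case means (1,2) vs (0,0), SDs 2, n = 1e5
  curves <- correlation_sweep_a2(base, c(-0.3, -0.1, 0.1, 0.3), 0.2,
                                 seed = 23)
  aucs <- vapply(curves, function(s) s$auc, numeric(1))
  expect_true(all(diff(aucs) < 0.005)) # decreasing in rho_case per step

  # shared correlations near +1 push discrimination up again
  hi <- simulate_population_a2(a2_spec(rho_case = 0.95, rho_control = 0.95),
                               24)
  mid <- simulate_population_a2(a2_spec(rho_case = 0.4, rho_control = 0.4),
                                24)
  auc_of <- function(co) {
    m <- fit_logistic(co)
    auc_mann_whitney(linear_predictor(m, co), co$y, "fixed")$auc
  }
  expect_gt(auc_of(hi), auc_of(mid) + 0.02)

  # shared rho -0.1 beats shared rho +0.2 (scenario-a geometry)
  neg <- simulate_population_a2(a2_spec(rho_case = -0.1, rho_control = -0.1),
                                25)
  pos <- simulate_population_a2(a2_spec(), 25)
  expect_lt(abs(auc_of(neg) - 0.795), 0.01)
  expect_lt(abs(auc_of(pos) - 0.770), 0.01)
})
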