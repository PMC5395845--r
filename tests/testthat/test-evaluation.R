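# Rank-based AUC, SD of the linear predictor, outcome-group summaries.

test_that("midrank AUC matches hand-derived pair counts and conventions", {
  expect_equal(auc_mann_whitney(c(3, 1, 2, 0), c(1, 0, 1, 0))$auc, 1)
  # brute force over the 4 case-control pairs: only (2 > 1) is concordant
  expect_identical(auc_bruteforce(c(1, 2, 0, 3), c(0, 1, 1, 0)), 0.25)
  fixed <- auc_mann_whitney(c(1, 2, 0, 3), c(0, 1, 1, 0), "fixed")
  expect_equal(fixed$auc, 0.25)
  expect_false(fixed$flipped)
  auto <- auc_mann_whitney(c(1, 2, 0, 3), c(0, 1, 1, 0), "auto")
  expect_equal(auto$auc, 0.75)
  expect_true(auto$flipped)
  expect_equal(auc_mann_whitney(rep(1, 10), rep_len(0:1, 10))$auc, 0.5)
  expect_error(auc_mann_whitney(1:5, rep(1, 5)), "cases and controls")
})

test_that("midrank AUC equals brute-force pairwise concordance", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(4:200, 1)
    # rounding forces ties so the midrank 1/2 convention is exercised
    scores <- round(rnorm(n), sample(0:1, 1))
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    expect_identical(auc_mann_whitney(scores, y)$auc, auc_bruteforce(scores, y))
  }
})

test_that("AUC is exactly invariant under increasing affine transforms", {
  set.seed(18)
  scores <- rnorm(300)
  y <- rbinom(300, 1, 0.3)
  y[1:2] <- 0:1
  a <- auc_mann_whitney(scores, y)$auc
  expect_identical(auc_mann_whitney(3.7 * scores - 11, y)$auc, a)
  expect_identical(auc_mann_whitney(plogis(scores), y)$auc, a)
})

test_that("midrank AUC agrees with an independent ROC implementation", {
  set.seed(19)
  scores <- rnorm(500)
  y <- rbinom(500, 1, 0.25)
  y[1:2] <- 0:1
  ours <- auc_mann_whitney(scores, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)
})

test_that("group summaries equal direct textbook moment formulas", {
  x <- rbind(c(1, 2), c(2, 1), c(3, 5), c(0, 1), c(-1, -2), c(4, 3))
  y <- c(1L, 1L, 1L, 0L, 0L, 0L)
  co <- aucmix:::new_cohort("toy", x, y, 0L)
  gs <- group_summaries(co)
  xc <- x[1:3, ]; xt <- x[4:6, ]
  expect_equal(gs$case$mu, c(x1 = 2, x2 = 8 / 3))
  expect_equal(gs$case$sigma, c(x1 = 1, x2 = sd(c(2, 1, 5))))
  expect_equal(gs$case$rho, cor(xc[, 1], xc[, 2]))
  expect_equal(gs$control$mu, colMeans(xt), ignore_attr = TRUE)
  expect_equal(gs$control$rho, cor(xt[, 1], xt[, 2]))

  y2 <- c(1L, 1L, rep(0L, 4))
  expect_error(group_summaries(aucmix:::new_cohort("toy", x, y2, 0L)),
               ">= 3 members")
})

test_that("exchangeable outcome groups show matching correlations", {
  spec <- a2_spec(mu_case = c(0, 0), mu_control = c(0, 0), rho_case = 0.3,
                  rho_control = 0.3)
  gs <- group_summaries(simulate_population_a2(spec, 91))
  expect_lt(abs(gs$case$rho - gs$control$rho), 0.02)
})

test_that("outcome conditioning shrinks the realized correlation (total rho 0.2 -> ~0.17)", {
  co <- simulate_population_a1(a1_spec(), seed = 92)
  gs <- group_summaries(co)
  expect_lt(abs(gs$case$rho - 0.17), 0.02)
  expect_lt(abs(gs$control$rho - 0.17), 0.02)
})

test_that("SD of the linear predictor matches its closed form and zero case", {
  co <- simulate_population_a1(a1_spec(n = 2000), seed = 93)
  expect_equal(sd_linear_predictor(aucmix:::new_risk_model(1, c(0, 0), "t"),
                                   co), 0)

  # strong second predictor: spread of the score rises to ~1.25
  coH <- simulate_population_a1(a1_spec(or = c(1.5, 3)), seed = 94)
  mH <- fit_logistic(coH)
  expect_lt(abs(sd_linear_predictor(mH, coH) - 1.25), 0.03)
  expect_lt(abs(sd_linear_predictor(mH, coH) -
                  sd_lp_closed_form(log(c(1.5, 3)), c(1, 1), 0.2)), 0.02)
})

test_that("evaluation reports carry consistent counts and summaries", {
  co <- simulate_population_a1(a1_spec(n = 2e4), seed = 95)
  m <- fit_logistic(co)
  r <- evaluate_model(m, co)
  expect_identical(r$n_cases + r$n_controls, cohort_size(co))
  expect_equal(r$sd_lp, sd_linear_predictor(m, co))
  expect_equal(r$auc, auc_mann_whitney(linear_predictor(m, co), co$y)$auc)
  expect_false(r$auc_direction_flipped)
  expect_gte(r$auc, 0.5) # in-sample ML fit concordance

  path <- withr::local_tempfile(fileext = ".csv")
  write_evaluation_csv(list(r), path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$auc, round(r$auc, 3))
  expect_equal(tab$sd_lp, round(r$sd_lp, 2))
})
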