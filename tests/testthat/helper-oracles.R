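# Independent oracles used to check the package's primitives.

# AUC by brute-force enumeration of all case-control pairs (ties = 1/2).
auc_bruteforce <- function(scores, y) {
  sc <- scores[y == 1]
  st <- scores[y == 0]
  tot <- 0
  for (a in sc) tot <- tot + sum(a > st) + 0.5 * sum(a == st)
  tot / (length(sc) * length(st))
}

# Intercept calibration by plain bisection on the mean risk.
calibrate_bisect <- function(x, betas, target, tol = 1e-10) {
  eta <- drop(x %*% betas)
  f <- function(b0) mean(plogis(b0 + eta)) - target
  lo <- -50; hi <- 50
  while (hi - lo > 1e-14) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < tol) break
  }
  (lo + hi) / 2
}

# Exact Bernoulli log-likelihood of a two-predictor logistic model.
loglik_logistic <- function(par, x, y) {
  eta <- par[1] + drop(x %*% par[2:3])
  sum(y * eta - log1p(exp(eta)))
}

# Coarse-to-fine grid search maximizer of the log-likelihood; independent of
# any IRLS/Newton machinery.
grid_fit_logistic <- function(x, y, center = c(0, 0, 0), width = 5,
                              rounds = 6, pts = 13) {
  best <- center
  for (r in seq_len(rounds)) {
    g1 <- seq(best[1] - width, best[1] + width, length.out = pts)
    g2 <- seq(best[2] - width, best[2] + width, length.out = pts)
    g3 <- seq(best[3] - width, best[3] + width, length.out = pts)
    val <- -Inf
    for (a in g1) for (b in g2) for (d in g3) {
      ll <- loglik_logistic(c(a, b, d), x, y)
      if (ll > val) { val <- ll; cand <- c(a, b, d) }
    }
    best <- cand
    width <- width * 2.2 / (pts - 1) # keep new grid overlapping old spacing
  }
  best
}

# Small Approach I spec shorthand for tests.
a1_spec <- function(id = "t", rho = 0.2, or = c(1.5, 1.5), mu = c(0, 0),
                    sigma = c(1, 1), n = 1e5, prevalence = 0.2) {
  population_spec_a1(id, rho = rho, adjusted_or = or, mu = mu, sigma = sigma,
                     n = n, prevalence = prevalence)
}

# Small Approach II spec shorthand (defaults = scenario with all SDs 2).
a2_spec <- function(id = "t", mu_case = c(1, 2), mu_control = c(0, 0),
                    sigma_case = c(2, 2), sigma_control = c(2, 2),
                    rho_case = 0.2, rho_control = 0.2, n = 1e5,
                    prevalence = 0.2) {
  population_spec_a2(id, mu_case = mu_case, mu_control = mu_control,
                     sigma_case = sigma_case, sigma_control = sigma_control,
                     rho_case = rho_case, rho_control = rho_control, n = n,
                     prevalence = prevalence)
}

# Closed-form SD of the linear predictor under an Approach I spec.
sd_lp_closed_form <- function(betas, sigma, rho) {
  sqrt(betas[1]^2 * sigma[1]^2 + betas[2]^2 * sigma[2]^2 +
         2 * rho * betas[1] * betas[2] * sigma[1] * sigma[2])
}
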