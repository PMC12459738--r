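test_that("noise-free trajectories are recovered exactly to optimizer
           tolerance", {
  truth <- default_truth()
  truth$qids <- lgcm_params(b00 = 5, b10 = -1)
  cfg <- generator_config(n_exp = 20, n_wait = 20, truth = truth,
                          dropout = rep(0, 4), seed = 8)
  dat <- generate_trial(cfg)
  fit <- fit_ml(dat, outcome = "qids",
                spec = lgcm_spec(arm = FALSE, gender = FALSE,
                                 cov01 = FALSE),
                fixed = c(var_e0 = 0, var_e1 = 0), se = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$params$b00, 5, tolerance = 1e-5)
  expect_equal(fit$params$b10, -1, tolerance = 1e-5)
})

test_that("tiny-instance FIML optimum matches brute-force grid plus
           polish", {
  set.seed(12)
  basis <- time_basis(c(0, 1))
  n <- 6
  y <- matrix(rnorm(n * 2, mean = c(3, 3, 3, 2, 2, 2)), n, 2)
  dat <- list(y = y, g_exp = rep(0, n), g_female = rep(0, n))
  fit <- fit_ml(dat, basis = basis,
                spec = lgcm_spec(arm = FALSE, gender = FALSE,
                                 cov01 = FALSE),
                fixed = c(var_e1 = 0), se = FALSE)
  # brute-force oracle over (b00, b10, log sd0, log sdr): coarse grid, then
  # Nelder-Mead polish from the best grid points
  negll <- function(th) {
    p <- lgcm_params(b00 = th[1], b10 = th[2], var_e0 = exp(2 * th[3]),
                     var_e2 = exp(2 * th[4]))
    -fiml_loglik(y, rep(0, n), rep(0, n), p, basis)
  }
  grid <- expand.grid(b00 = seq(1, 5, length.out = 7),
                      b10 = seq(-3, 2, length.out = 7),
                      l0 = seq(-3, 1.5, length.out = 6),
                      lr = seq(-3, 1.5, length.out = 6))
  vals <- apply(grid, 1, negll)
  best <- order(vals)[1:5]
  polished <- min(vapply(best, function(i) {
    optim(as.numeric(grid[i, ]), negll, method = "Nelder-Mead",
          control = list(maxit = 5000, reltol = 1e-12))$value
  }, numeric(1)))
  expect_equal(fit$loglik, -polished, tolerance = 1e-4)
})

test_that("Wald mapping gives the standard z, p and CI", {
  w <- wald_test(2.321, 1)
  expect_equal(round(w$pvalue, 3), 0.020)
  w2 <- wald_test(-2.703, 1)
  expect_equal(round(w2$pvalue, 3), 0.007)
  w3 <- wald_test(0, 2)
  expect_equal(w3$z, 0)
  expect_equal(w3$pvalue, 1)
  expect_equal(unname(w3$ci95[1, ]), c(-2, 2) * 1.959964)
  expect_error(wald_test(1, 0), "positive")
  # CI and z are consistent: z = beta/se, ci = beta +/- 1.959964 se
  w4 <- wald_test(0.195, 0.084)
  expect_equal(w4$z, 0.195 / 0.084)
  expect_equal(unname(w4$ci95[1, ]),
               0.195 + c(-1, 1) * 1.959964 * 0.084)
})

test_that("freeing the intervention slope never lowers the maximized
           likelihood", {
  dat <- small_trial(seed = 31, n = 80)
  full <- fit_ml(dat, outcome = "qids", se = FALSE)
  null <- fit_ml(dat, outcome = "qids", fixed = c(b1exp = 0), se = FALSE)
  expect_gte(full$loglik, null$loglik - 1e-6)
})

test_that("FIML is unbiased under 20% MCAR deletion", {
  truth <- default_truth()
  cfg <- generator_config(n_exp = 600, n_wait = 600, truth = truth,
                          dropout = c(0, 0.2, 0.2, 0.2), seed = 17)
  dat <- generate_trial(cfg)
  fit <- fit_ml(dat, outcome = "qids")
  row <- fit$coef[fit$coef$term == "b1exp", ]
  expect_true(fit$converged)
  expect_lt(abs(row$beta - truth$qids$b1exp), 3 * row$se)
})

test_that("complete-data estimates agree with an independent mixed-model
           fit", {
  skip_if_not_installed("lme4")
  cfg <- generator_config(n_exp = 250, n_wait = 250, dropout = rep(0, 4),
                          seed = 23)
  dat <- generate_trial(cfg)
  fit <- fit_ml(dat, outcome = "qids", se = FALSE)
  long <- trial_long(dat)
  long$g_exp <- as.integer(long$arm == "experimental")
  lf <- lme4::lmer(
    qids ~ loading + g_exp + female + g_exp:loading + female:loading +
      (loading | id),
    data = long, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(lf)
  expect_equal(fit$params$b00, unname(fe["(Intercept)"]), tolerance = 1e-3)
  expect_equal(fit$params$b1exp, unname(fe["loading:g_exp"]),
               tolerance = 1e-3)
  expect_equal(fit$params$b0exp, unname(fe["g_exp"]), tolerance = 1e-3)
  expect_equal(fit$params$b10, unname(fe["loading"]), tolerance = 1e-3)
  # same likelihood up to the tiny diagonal jitter
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 0.5)
})

test_that("posterior mean matches the conjugate closed form in a known-
           variance single-wave model", {
  set.seed(41)
  n <- 60
  sigma2 <- 4
  y <- matrix(rnorm(n, mean = 3, sd = sqrt(sigma2)), n, 1)
  dat <- list(y = y, g_exp = rep(0, n), g_female = rep(0, n))
  post <- sample_posterior(dat, basis = time_basis(0),
                           spec = lgcm_spec(arm = FALSE, gender = FALSE,
                                            slope = FALSE),
                           fixed = c(var_e0 = 0, var_e2 = sigma2),
                           n_chains = 2, n_iter = 4000, burn = 2000,
                           thin = 2, seed = 7)
  draws <- do.call(rbind, post$draws)[, "b00"]
  # wide normal prior: posterior essentially N(ybar, (sigma2+jitter)/n)
  expect_lt(abs(mean(draws) - mean(y)),
            3 * sd(draws) / sqrt(200))  # conservative effective sample size
  expect_lt(abs(sd(draws) - sqrt((sigma2 + 1e-4) / n)), 0.05)
})

test_that("identical chain seeds reproduce identical draws and leave R-hat
           well defined", {
  dat <- small_trial(seed = 2, n = 25)
  run <- function() {
    sample_posterior(dat, outcome = "qids",
                     spec = lgcm_spec(gender = FALSE, cov01 = FALSE),
                     n_chains = 2, n_iter = 2000, burn = 2000, thin = 4,
                     seed = 9, chain_seeds = c(5, 5))
  }
  p1 <- run()
  p2 <- run()
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$draws[[1]], p1$draws[[2]])
  expect_true(all(is.finite(p1$rhat)))
  expect_true(all(p1$rhat < 1.05))
})

test_that("split R-hat handles identical, well-mixed and degenerate
           chains", {
  set.seed(6)
  x <- matrix(rnorm(500), ncol = 1)
  # identical chains: R-hat at 1 up to split noise
  expect_lt(gelman_rubin(list(x, x)) , 1 + 0.01)
  # independent chains from the same distribution: near 1
  y <- matrix(rnorm(500), ncol = 1)
  expect_lt(gelman_rubin(list(x, y)), 1.02)
  # the split formula can dip marginally below 1 when B < W
  expect_gt(gelman_rubin(list(x, y)), 0.99)
  # constant chains at different values: infinite by convention
  c1 <- matrix(1, 50, 1); c2 <- matrix(2, 50, 1)
  expect_identical(unname(gelman_rubin(list(c1, c2))), Inf)
  # constant chains at the same value: no variation at all
  expect_identical(unname(gelman_rubin(list(c1, c1))), 1)
  expect_error(gelman_rubin(list(matrix(1, 2, 1), matrix(1, 2, 1))),
               ">= 4 draws")
})

test_that("WAIC and LOO match their formulas on hand matrices", {
  # single draw: zero penalty
  ll1 <- matrix(c(-1.2, -0.7, -2.1), 1, 3)
  w1 <- waic(ll1)
  expect_equal(unname(w1["p_waic"]), 0)
  expect_equal(unname(w1["elpd_waic"]), sum(ll1))
  expect_equal(unname(w1["waic"]), -2 * sum(ll1))
  # identical draws: degenerate posterior, LOO equals WAIC
  ll2 <- matrix(rep(c(-1, -2), each = 3), 3, 2)
  expect_equal(unname(waic(ll2)["p_waic"]), 0)
  expect_equal(unname(loo(ll2)["elpd_loo"]), unname(waic(ll2)["elpd_waic"]))
  # 3 x 2 hand matrix against direct formula evaluation
  ll <- matrix(c(-1.0, -1.5, -0.8,
                 -2.0, -1.2, -1.7), 3, 2)
  lpd <- apply(ll, 2, function(l) log(mean(exp(l))))
  pw <- apply(ll, 2, var)
  expect_equal(unname(waic(ll)["elpd_waic"]), sum(lpd - pw),
               tolerance = 1e-12)
  expect_equal(unname(waic(ll)["waic"]), -2 * sum(lpd - pw),
               tolerance = 1e-12)
  # direct truncated-importance-sampling evaluation
  S <- nrow(ll)
  elpd_loo <- sum(vapply(1:2, function(i) {
    w <- exp(-ll[, i])
    w <- pmin(w, mean(w) * S^0.75)
    log(sum(w * exp(ll[, i])) / sum(w))
  }, numeric(1)))
  expect_equal(unname(loo(ll)["elpd_loo"]), elpd_loo, tolerance = 1e-12)
  # LOO never beats the in-sample log pointwise density
  expect_lte(unname(loo(ll)["elpd_loo"]), sum(lpd) + 1e-12)
  expect_error(waic(matrix(c(1, NA), 2, 1)), "non-finite")
})

test_that("WAIC/LOO are invariant to participant reordering", {
  set.seed(13)
  ll <- matrix(rnorm(200, -2), 20, 10)
  perm <- sample(10)
  expect_equal(waic(ll), waic(ll[, perm]))
  expect_equal(as.numeric(loo(ll)), as.numeric(loo(ll[, perm])))
})

test_that("doubling the posterior sample leaves elpd_waic stable", {
  dat <- small_trial(seed = 3, n = 30)
  spec <- lgcm_spec(gender = FALSE, cov01 = FALSE)
  p1 <- sample_posterior(dat, outcome = "qids", spec = spec, n_chains = 2,
                         n_iter = 1500, burn = 1500, thin = 3, seed = 11)
  p2 <- sample_posterior(dat, outcome = "qids", spec = spec, n_chains = 2,
                         n_iter = 3000, burn = 1500, thin = 3, seed = 12)
  # scale of elpd noise: spread of per-draw total log-likelihood
  tot <- rowSums(p1$pointwise_loglik)
  mc_se <- 3 * sd(tot) / sqrt(length(tot) / 10)  # generous autocorrelation
  expect_lt(abs(p1$waic["elpd_waic"] - p2$waic["elpd_waic"]),
            max(mc_se, 3))
})
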