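test_that("fixed-variance BRR matches the closed-form ridge posterior mean", {
  set.seed(31)
  n <- 120; p <- 40
  Z <- scale(matrix(rnorm(n * p), n), scale = FALSE)
  theta_true <- rnorm(p, 0, 0.5)
  y <- drop(Z %*% theta_true) + rnorm(n, 0, 0.5)
  var_e <- 0.25; var_b <- 0.25
  oracle <- ridge_posterior_mean(Z, y, var_e, var_b)
  fit <- gibbs_shrinkage(y, Z, "BRR", n_iter = 20000, burn_in = 2000,
                         thin = 2, seed = 99,
                         fix = list(var_e = var_e, var_b = var_b))
  mc_se <- apply(fit$draws$theta, 2, sd) / sqrt(fit$n_save)
  expect_true(all(abs(fit$coef - oracle) < 3 * mc_se))
})

test_that("every prior collapses to the ridge conditional when its hierarchy is fixed", {
  set.seed(32)
  n <- 100; p <- 25
  Z <- scale(matrix(rnorm(n * p), n), scale = FALSE)
  y <- drop(Z %*% rnorm(p, 0, 0.6)) + rnorm(n, 0, 0.5)
  var_e <- 0.25; var_b <- 0.36
  oracle <- ridge_posterior_mean(Z, y, var_e, var_b)
  for (prior in c("BayesA", "BayesB", "BayesC", "BL")) {
    fit <- gibbs_shrinkage(y, Z, prior, n_iter = 16000, burn_in = 2000,
                           thin = 2, seed = 77,
                           fix = list(var_e = var_e, var_b = var_b,
                                      pi = 1, lambda2 = 1))
    mc_se <- apply(fit$draws$theta, 2, sd) / sqrt(fit$n_save)
    expect_true(all(abs(fit$coef - oracle) < 3.5 * mc_se),
                label = sprintf("%s conjugate limit", prior))
  }
})

test_that("a null response yields coefficients indistinguishable from zero", {
  set.seed(33)
  Z <- matrix(rnorm(80 * 15), 80)
  fit <- gibbs_shrinkage(rep(0, 80), Z, "BRR", n_iter = 4000,
                         burn_in = 1000, seed = 5)
  mc_se <- apply(fit$draws$theta, 2, sd) / sqrt(fit$n_save)
  expect_true(all(abs(fit$coef) < 3 * pmax(mc_se, 1e-8)))
})

test_that("identical seeds give bitwise-identical draws; validation errors fire", {
  set.seed(34)
  Z <- matrix(rnorm(50 * 8), 50)
  y <- rnorm(50)
  f1 <- gibbs_shrinkage(y, Z, "BayesB", n_iter = 600, burn_in = 100, seed = 3)
  f2 <- gibbs_shrinkage(y, Z, "BayesB", n_iter = 600, burn_in = 100, seed = 3)
  expect_identical(f1$draws, f2$draws)
  expect_error(gibbs_shrinkage(c(y, NA), rbind(Z, 1), "BRR"), "finite")
  expect_error(gibbs_shrinkage(y, Z, "BRR", n_iter = 100, burn_in = 100),
               "burn_in")
  expect_error(gibbs_shrinkage(y[1:2], Z[1:2, ], "BRR"), "at least 3")
})

test_that("draw bookkeeping matches the chain configuration", {
  set.seed(35)
  Z <- matrix(rnorm(40 * 6), 40)
  fit <- gibbs_shrinkage(rnorm(40), Z, "BL", n_iter = 1100, burn_in = 100,
                         thin = 4, seed = 2)
  expect_identical(fit$n_save, 250L)
  expect_identical(dim(fit$draws$theta), c(250L, 6L))
  expect_true(all(fit$draws$var_e > 0))
})

test_that("posterior-mean prediction follows its definition and interpolates strong signal", {
  set.seed(36)
  n <- 90; p <- 12
  Z <- matrix(rnorm(n * p), n)
  y <- drop(Z %*% rnorm(p)) # noiseless
  fit <- gibbs_shrinkage(y, Z, "BRR", n_iter = 3000, burn_in = 1000, seed = 8)
  pred <- predict(fit, Z)
  manual <- fit$intercept +
    drop(sweep(Z, 2, fit$col_means, "-") %*% fit$coef)
  expect_identical(pred, manual)
  expect_gt(pearson_r(pred, y), 0.999)
  expect_error(predict(fit, Z[, 1:5]), "columns")
  # no-signal fit predicts the response mean
  y0 <- rnorm(n)
  Z0 <- matrix(0.5, n, 3) + matrix(rnorm(n * 3, 0, 1e-8), n)
  fit0 <- gibbs_shrinkage(y0, Z0, "BRR", n_iter = 2000, burn_in = 500,
                          seed = 9)
  expect_lt(max(abs(predict(fit0, Z0) - mean(y0))), 0.2)
})

test_that("coefficient recovery on a reduced-design functional problem", {
  set.seed(37)
  n <- 300; L <- 23
  b <- basis_bspline(c(392, 851), 3, 19)
  # curves drawn from the same basis family the design projects onto, so the
  # coefficient vector is identified
  sim <- simulate_curves(n = n, m = 120, truth_basis = b, seed = 37)
  Z <- design_matrix(sim$data, "M6", b)$Z
  Zc <- scale(Z, scale = FALSE)
  d_true <- rnorm(L)
  signal <- drop(Zc %*% d_true)
  y <- signal + rnorm(n, 0, sd(signal) / 3)
  fit <- gibbs_shrinkage(y, Z, "BRR", n_iter = 3000, burn_in = 1000, seed = 38)
  expect_gt(pearson_r(fit$coef, d_true), 0.9)
})

test_that("beta_curve reconstructs the coefficient function from basis fits", {
  sim <- make_pheno_sim(n = 120, m = 100, seed = 41)
  fb <- basis_fourier(c(392, 851), 23)
  fit <- fit_bfr(sim$data, method = "M7", basis = fb, prior = "BRR",
                 n_iter = 2500, burn_in = 500, thin = 2, seed = 42)
  bc <- beta_curve(fit)
  truth <- sin(2 * pi * sim$data$grid / 459)
  expect_gt(abs(pearson_r(bc$estimate, truth)), 0.9)
  expect_true(all(bc$lower <= bc$estimate & bc$estimate <= bc$upper))
  # nested grids agree pointwise
  g2 <- sim$data$grid[seq(1, 100, by = 2)]
  bc2 <- beta_curve(fit, t = g2)
  expect_equal(bc2$estimate, bc$estimate[seq(1, 100, by = 2)])
  # constant single-basis system: beta is the lone coefficient everywhere
  f1 <- basis_fourier(c(392, 851), 1)
  fit1 <- fit_bfr(sim$data, method = "M7", basis = f1, prior = "BRR",
                  n_iter = 800, burn_in = 300, seed = 43)
  bc1 <- beta_curve(fit1, t = c(400, 600, 800))
  expect_equal(bc1$estimate, rep(fit1$posterior$coef, 3))
  # per-band fits refuse beta_curve but expose pointwise coefficients
  fitm1 <- fit_bfr(sim$data, method = "M1", prior = "BRR",
                   n_iter = 600, burn_in = 200, seed = 44)
  expect_error(beta_curve(fitm1), "pointwise_coefficients")
  expect_equal(nrow(pointwise_coefficients(fitm1)), 100)
  expect_error(pointwise_coefficients(fit), "M1/M4/M5")
})

test_that("null-data inclusion probabilities stay near the prior mean", {
  set.seed(45)
  n <- 100; p <- 50
  Z <- matrix(rnorm(n * p), n)
  y <- rnorm(n)
  for (prior in c("BayesB", "BayesC")) {
    fit <- gibbs_shrinkage(y, Z, prior, n_iter = 4000, burn_in = 1000,
                           seed = 46)
    mean_pi <- mean(fit$inclusion_prob)
    mc_se <- sd(fit$inclusion_prob) / sqrt(p)
    expect_lt(mean_pi, 0.5 + 3 * mc_se)
  }
})

test_that("spike-and-slab priors beat ridge on sparse truth", {
  n <- 150; p <- 100
  wins <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    Z <- matrix(rnorm(n * p), n)
    theta <- c(rnorm(5, 0, 1), rep(0, p - 5))
    y <- drop(Z %*% theta) + rnorm(n, 0, 0.5)
    rmse <- function(prior) {
      f <- gibbs_shrinkage(y, Z, prior, n_iter = 1200, burn_in = 400,
                           thin = 2, seed = 2000 + s)
      sqrt(mean((f$coef - theta)^2))
    }
    rmse("BayesB") < rmse("BRR")
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("tidy and glance expose the posterior in broom conventions", {
  sim <- make_pheno_sim(n = 50, m = 60, seed = 51)
  b <- basis_bspline(c(392, 851), 3, 7)
  fit <- fit_bfr(sim$data, method = "M6", basis = b, prior = "BayesC",
                 n_iter = 600, burn_in = 200, seed = 52)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high", "inclusion_prob"))
  expect_equal(nrow(td), 11 + 2) # L coefficients + intercept + sigma2
  expect_true(all(td$conf.low <= td$conf.high))
  gl <- glance(fit)
  expect_identical(gl$method, "M6")
  expect_identical(gl$prior, "BayesC")
  expect_true(is.numeric(gl$r_train))
})
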