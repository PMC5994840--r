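# Shared test oracles, independent of the implementation paths they check.

# Rank-aware least-squares fitted values: projection of y onto the column
# space of Z via the SVD (robust to heavy rank deficiency, unlike pivoted QR).
ols_fitted_svd <- function(Z, y, tol = 1e-8) {
  s <- svd(Z)
  keep <- s$d > s$d[1] * tol
  U <- s$u[, keep, drop = FALSE]
  drop(U %*% crossprod(U, y))
}

rank_svd <- function(Z, tol = 1e-8) {
  d <- svd(Z)$d
  sum(d > d[1] * tol)
}

# Normal-equations smoother, the literal textbook formula.
coef_normal_equations <- function(Phi, x) {
  drop(solve(crossprod(Phi), crossprod(Phi, x)))
}

# Closed-form ridge posterior mean with fixed variances, on centered Z.
ridge_posterior_mean <- function(Z, y, var_e, var_b) {
  p <- ncol(Z)
  drop(solve(crossprod(Z) + diag(var_e / var_b, p), crossprod(Z, y - mean(y))))
}

# Dense Riemann (midpoint) approximation to integral f(t) g(t) dt.
riemann_inner <- function(f, g, lo, hi, n = 1e6) {
  t <- seq(lo, hi, length.out = n + 1)
  mid <- (t[-1] + t[-length(t)]) / 2
  sum(f(mid) * g(mid)) * (hi - lo) / n
}

# RMSE of a smoother reconstruction against the true function values.
sine_smooth_rmse <- function(sim, basis) {
  sm <- smooth_curves(matrix(sim$x, 1), basis, grid = sim$t)
  sqrt(mean((drop(sm$fitted) - sim$truth)^2))
}

# A small wheat-like simulated dataset with phenotypes, shared across tests.
make_pheno_sim <- function(n = 60, m = 100, seed = 1, beta_period = 459,
                           residual_sd = NULL, noise_sd = 0.1) {
  sim <- simulate_curves(n = n, m = m, noise_sd = noise_sd, seed = seed)
  simulate_phenotypes(sim, beta = function(t) sin(2 * pi * t / beta_period),
                      residual_sd = residual_sd, seed = seed + 1000)
}

fast_mcmc <- list(n_iter = 800, burn_in = 300, thin = 2)
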