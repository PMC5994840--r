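test_that("in-span curves are reconstructed exactly", {
  set.seed(1)
  grid <- seq(392, 851, length.out = 120)
  b <- basis_bspline(c(392, 851), 3, 10)
  Phi <- evaluate_basis(b, grid)
  C0 <- matrix(rnorm(5 * n_basis(b)), 5)
  X <- C0 %*% t(Phi)
  sm <- smooth_curves(X, b, grid = grid)
  expect_lt(max(abs(sm$coef - C0)) / max(abs(C0)), 1e-8)
  expect_lt(max(abs(sm$fitted - X)), 1e-8)
  # constant curve reproduced exactly by partition of unity
  smc <- smooth_curves(matrix(5, 1, 120), b, grid = grid)
  expect_equal(drop(smc$fitted), rep(5, 120), tolerance = 1e-10)
})

test_that("coefficients match the normal-equations oracle on random problems", {
  set.seed(2)
  for (i in 1:100) {
    m <- sample(30:80, 1)
    q <- sample(1:3, 1)
    K <- sample(0:6, 1)
    grid <- sort(runif(m, 0, 1))
    b <- basis_bspline(c(0, 1), q, K)
    x <- rnorm(m)
    sm <- smooth_curves(matrix(x, 1), b, grid = grid)
    oracle <- coef_normal_equations(evaluate_basis(b, grid), x)
    expect_lt(max(abs(drop(sm$coef) - oracle)), 1e-8)
  }
})

test_that("smoothing is idempotent and RSS is monotone in nested systems", {
  set.seed(3)
  grid <- seq(0, 1, length.out = 200)
  x <- matrix(sin(6 * grid) + rnorm(200, 0, 0.3), 1)
  b <- basis_bspline(c(0, 1), 3, 7)
  sm1 <- smooth_curves(x, b, grid = grid)
  sm2 <- smooth_curves(sm1$fitted, b, grid = grid)
  expect_lt(max(abs(sm2$fitted - sm1$fitted)), 1e-10)
  # uniform knots with K doubling are nested: 2^k spans refine
  rss <- vapply(c(1, 3, 7, 15), function(K) {
    sm <- smooth_curves(x, basis_bspline(c(0, 1), 3, K), grid = grid)
    sum((x - sm$fitted)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("sine-simulation smoothing beats the measurement noise", {
  sim <- simulate_sine(100, seed = 11)
  b <- basis_bspline(range(sim$t), 3, 21) # cubic, L = 25
  rmse <- sine_smooth_rmse(sim, b)
  expect_lt(rmse, 0.5)
  # against the independent normal-equations solve on the same data
  Phi <- evaluate_basis(b, sim$t)
  oracle_fit <- drop(Phi %*% coef_normal_equations(Phi, sim$x))
  sm <- smooth_curves(matrix(sim$x, 1), b, grid = sim$t)
  expect_lt(max(abs(drop(sm$fitted) - oracle_fit)), 1e-8)
})

test_that("residual sd estimates recover the simulated noise level", {
  sim <- simulate_curves(n = 200, m = 250, noise_sd = 0.5, seed = 21)
  b <- sim$truth$basis # generous: the truth basis itself
  sm <- smooth_curves(sim$data, b)
  expect_gt(mean(sm$residual_sd), 0.45)
  expect_lt(mean(sm$residual_sd), 0.55)
})

test_that("rank-deficient configurations are rejected with context", {
  grid <- seq(0, 1, length.out = 30)
  b <- basis_bspline(c(0, 1), 3, 40) # L = 44 > m
  expect_error(smooth_curves(matrix(rnorm(30), 1), b, grid = grid),
               "exceeds grid size")
  # Fourier aliasing: frequencies beyond Nyquist collapse on a coarse grid
  g4 <- seq(0, 1, length.out = 5)
  fb <- basis_fourier(c(0, 1), 5, period = 1)
  expect_error(smooth_curves(matrix(rnorm(5), 1), fb, grid = g4),
               "rank-deficient")
})

test_that("GCV and R2 knot selection match brute-force enumeration", {
  set.seed(4)
  grid <- seq(0, 1, length.out = 150)
  b4 <- basis_bspline(c(0, 1), 3, 4)
  truth <- drop(evaluate_basis(b4, grid) %*% rnorm(n_basis(b4)))
  cands <- c(0L, 2L, 4L, 8L, 16L)
  # noise-free curve in the span of K = 4: r2 picks the first K with RSS ~ 0
  sel <- select_knots(matrix(truth, 1), degree = 3, candidates = cands,
                      criterion = "r2", r2_threshold = 0.999, grid = grid)
  expect_identical(sel$K, 4L)
  # brute-force score table oracle
  brute <- vapply(cands, function(K) {
    Phi <- evaluate_basis(basis_bspline(c(0, 1), 3, K), grid)
    sum((truth - Phi %*% coef_normal_equations(Phi, truth))^2)
  }, numeric(1))
  expect_equal(sel$scores$rss, brute, tolerance = 1e-8)
  m <- length(grid)
  expect_equal(sel$scores$gcv,
               (brute / m) / (1 - (3 + 1 + cands) / m)^2, tolerance = 1e-8)
  # gcv agrees with the brute-force minimiser on a noisy curve
  x <- truth + rnorm(m, 0, 0.2)
  sel_g <- select_knots(matrix(x, 1), degree = 3, candidates = cands,
                        criterion = "gcv", grid = grid)
  brute_g <- vapply(cands, function(K) {
    L <- 3 + 1 + K
    Phi <- evaluate_basis(basis_bspline(c(0, 1), 3, K), grid)
    rss <- sum((x - Phi %*% coef_normal_equations(Phi, x))^2)
    (rss / m) / (1 - L / m)^2
  }, numeric(1))
  expect_identical(sel_g$K, cands[which.min(brute_g)])
})

test_that("GCV prefers no knots on pure white noise", {
  grid <- seq(0, 1, length.out = 100)
  picks <- vapply(1:50, function(s) {
    set.seed(s)
    x <- matrix(rnorm(100), 1)
    select_knots(x, degree = 3, candidates = c(0, 2, 4, 8, 16),
                 criterion = "gcv", grid = grid)$K
  }, integer(1))
  expect_gt(mean(picks == 0), 0.5)
})

test_that("knot-selection edge cases follow the contract", {
  grid <- seq(0, 1, length.out = 50)
  x <- matrix(rnorm(50), 1)
  for (crit in c("gcv", "r2")) {
    expect_identical(
      select_knots(x, candidates = 3, criterion = crit, r2_threshold = 0,
                   grid = grid)$K, 3L)
  }
  expect_error(select_knots(x, candidates = integer(0), grid = grid),
               "non-empty")
  expect_warning(
    sel <- select_knots(x, candidates = c(0, 2), criterion = "r2",
                        r2_threshold = 0.999999, grid = grid),
    "largest")
  expect_identical(sel$K, 2L)
})
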