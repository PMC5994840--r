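#' Simulate the noisy-sine smoothing benchmark
#'
#' Generates the classic one-curve smoothing testbed: points `t_k` drawn
#' uniformly on `[10, 20]` (returned sorted, with the original draw order kept
#' as a column), observations `x_k = sin(1 + t_k) + eps_k` with i.i.d.
#' Gaussian noise of standard deviation 0.5, and the noise-free truth
#' `f(t) = sin(1 + t)`.
#'
#' @param n_points Number of points (default 100).
#' @param seed Integer seed.
#' @param noise_sd Measurement-noise standard deviation.
#' @param domain Sampling interval for `t`.
#' @return A tibble with columns `t` (sorted), `order` (original draw index),
#'   `x` (noisy value) and `truth`.
#' @export
simulate_sine <- function(n_points = 100, seed = NULL, noise_sd = 0.5,
                          domain = c(10, 20)) {
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_raw <- stats::runif(n_points, domain[1], domain[2])
  x_raw <- sin(1 + t_raw) + stats::rnorm(n_points, 0, noise_sd)
  ord <- order(t_raw)
  tibble::tibble(t = t_raw[ord], order = ord, x = x_raw[ord],
                 truth = sin(1 + t_raw[ord]))
}

#' Simulate hyperspectral-like curve data with known smooth truth
#'
#' Emulates a reflectance band matrix: each sample's true curve is a random
#' linear combination of a smooth truth basis, `f_i = Phi_truth c_i` with
#' `c_i ~ N(0, coef_sd^2 I)`, observed on an equispaced grid of `m` points
#' with i.i.d. Gaussian measurement noise. Defaults mirror a wheat
#' hyperspectral campaign: 250 wavelengths spanning 392–851 nm, curves of
#' roughly unit variance built from a cubic B-spline truth basis with
#' `L = 15`.
#'
#' @param n Number of samples (curves).
#' @param m Number of measurement points.
#' @param domain Grid endpoints.
#' @param truth_basis `basis_system` generating the smooth truth (default:
#'   cubic B-spline with 11 interior knots, `L = 15`).
#' @param coef_sd Standard deviation of the truth-basis coefficients.
#' @param noise_sd Measurement-noise standard deviation.
#' @param seed Integer seed.
#' @return A `bfr_sim` list: `data` (an [fdata()] without response) and
#'   `truth` (`curves` — the noise-free `n x m` matrix, `basis`, `coef`,
#'   `noise_sd`, `seed`).
#' @export
simulate_curves <- function(n, m = 250, domain = c(392, 851),
                            truth_basis = NULL, coef_sd = 1, noise_sd = 0.1,
                            seed = NULL) {
  if (n < 1 || m < 2) stop("need n >= 1 and m >= 2", call. = FALSE)
  if (coef_sd < 0 || noise_sd < 0) {
    stop("coef_sd and noise_sd must be >= 0", call. = FALSE)
  }
  if (is.null(truth_basis)) {
    truth_basis <- basis_bspline(domain, degree = 3, n_knots = 11)
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(domain[1], domain[2], length.out = m)
  Phi <- evaluate_basis(truth_basis, grid)
  L <- n_basis(truth_basis)
  coef <- matrix(stats::rnorm(n * L, 0, coef_sd), n, L)
  curves <- coef %*% t(Phi)
  X <- curves + matrix(stats::rnorm(n * m, 0, noise_sd), n, m)
  structure(
    list(data = fdata(X, grid),
         truth = list(curves = curves, basis = truth_basis, coef = coef,
                      coef_sd = coef_sd, noise_sd = noise_sd, seed = seed)),
    class = "bfr_sim")
}

#' @export
print.bfr_sim <- function(x, ...) {
  cat(sprintf("<synthetic curves> %d x %d, noise sd %g%s\n",
              nrow(x$data$X), ncol(x$data$X), x$truth$noise_sd,
              if (is.null(x$data$y)) "" else ", with simulated response"))
  invisible(x)
}

# Evaluate a coefficient-function specification on a grid
eval_beta_spec <- function(beta, grid) {
  if (is.function(beta)) return(beta(grid))
  if (is.list(beta) && inherits(beta$basis, "basis_system")) {
    return(drop(evaluate_basis(beta$basis, grid) %*% beta$coef))
  }
  if (is.numeric(beta) && length(beta) %in% c(1L, length(grid))) {
    return(rep_len(beta, length(grid)))
  }
  stop("beta must be a function, list(basis=, coef=), or numeric", call. = FALSE)
}

#' Simulate phenotypes from a functional linear model
#'
#' Adds a scalar response to a simulated curve set according to
#' `y_i = integral f_i(t) beta(t) dt + e_i`, where `f_i` are the *noise-free*
#' truth curves (so the target signal is exactly the functional model), the
#' integral is trapezoid quadrature over the grid, and
#' `e_i ~ N(0, residual_sd^2)`.
#'
#' @param sim A `bfr_sim` from [simulate_curves()].
#' @param beta Coefficient function: an R function of `t`, a
#'   `list(basis =, coef =)` pair, or a numeric constant/vector on the grid.
#' @param residual_sd Residual standard deviation of `y`; `NULL` (default)
#'   sets it to `sd(signal) / 3`, i.e. a 3:1 signal-to-noise ratio.
#' @param seed Integer seed.
#' @return The `bfr_sim` with `data$y` filled in and `truth` augmented with
#'   `beta` (values on the grid), `signal` (the noise-free integrals) and
#'   `residual_sd`.
#' @export
simulate_phenotypes <- function(sim, beta, residual_sd = NULL, seed = NULL) {
  stopifnot(inherits(sim, "bfr_sim"))
  grid <- sim$data$grid
  beta_vals <- eval_beta_spec(beta, grid)
  if (any(!is.finite(beta_vals))) stop("beta is non-finite on the grid",
                                       call. = FALSE)
  signal <- apply(sim$truth$curves, 1, function(f) {
    pracma::trapz(grid, f * beta_vals)
  })
  if (is.null(residual_sd)) {
    residual_sd <- stats::sd(signal) / 3
    if (!is.finite(residual_sd)) residual_sd <- 1
  }
  if (residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- signal + stats::rnorm(length(signal), 0, residual_sd)
  sim$data <- fdata(sim$data$X, grid, y = y, ids = sim$data$ids)
  sim$truth$beta <- beta_vals
  sim$truth$signal <- signal
  sim$truth$residual_sd <- residual_sd
  sim$truth$phenotype_seed <- seed
  sim
}
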