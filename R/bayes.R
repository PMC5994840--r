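#' Gibbs sampler for shrinkage regression
#'
#' Fits `y = mu + Z theta + e`, `e ~ N(0, var_e I)`, by Gibbs sampling under
#' one of five shrinkage priors for `theta`:
#'
#' * `BRR` — Bayesian ridge: common Gaussian prior `N(0, var_b)`.
#' * `BayesA` — coefficient-specific variances with scaled-inverse-chi-square
#'   priors (marginally scaled-t).
#' * `BayesB` — spike at zero plus BayesA slab, Bernoulli inclusion with a
#'   Beta-updated inclusion probability `pi`.
#' * `BayesC` — spike plus common-variance Gaussian slab.
#' * `BL` — Bayesian lasso: double-exponential prior via its exponential
#'   scale mixture (Park & Casella).
#'
#' The intercept carries a flat prior; the residual and coefficient variances
#' carry scaled-inverse-chi-square priors whose scales are set from the prior
#' variance partition `R2` (proportion of `var(y)` attributed to the linear
#' term, default 0.5) and the column sums of squares of `Z` — the de-facto
#' defaults of whole-genome-regression software. Coefficients are updated in
#' fixed column order each sweep from a single RNG stream, so runs are
#' bitwise reproducible given `seed`.
#'
#' @param y Numeric response, length `n >= 3`.
#' @param Z Numeric `n x p` design matrix.
#' @param prior One of `"BRR"`, `"BayesA"`, `"BayesB"`, `"BayesC"`, `"BL"`.
#' @param n_iter,burn_in,thin MCMC chain length, warm-up, and thinning.
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @param center Center the columns of `Z` before fitting (means are stored
#'   and re-applied at prediction). Default `TRUE`.
#' @param standardize Additionally scale columns to unit standard deviation.
#' @param R2 Prior variance partition in `(0, 1)`.
#' @param hyper Named list of hyperparameter overrides: `df_e`, `S_e`, `df_b`,
#'   `S_b`, `pi0`, `p0` (Beta prior counts are `p0*pi0`, `p0*(1-pi0)`),
#'   `lambda_shape`, `lambda_rate`.
#' @param fix Named list pinning parts of the hierarchy for diagnostics:
#'   `var_e`, `var_b` (for `BL` this freezes the scale mixture at
#'   `var_b`), `pi`, `lambda2`. With `var_e` and `var_b` fixed every family
#'   collapses to the conjugate ridge conditional.
#' @return A `bfr_gibbs` object with posterior draws (`theta` is
#'   `n_save x p`), posterior means, and fitting metadata.
#' @export
gibbs_shrinkage <- function(y, Z,
                            prior = c("BRR", "BayesA", "BayesB", "BayesC", "BL"),
                            n_iter = 6000, burn_in = 1000, thin = 5,
                            seed = NULL, center = TRUE, standardize = FALSE,
                            R2 = 0.5, hyper = list(), fix = list()) {
  prior <- match.arg(prior)
  y <- as.numeric(y)
  Z <- as.matrix(Z)
  n <- length(y); p <- ncol(Z)
  if (any(!is.finite(y)) || any(!is.finite(Z))) {
    stop("y and Z must be finite", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (nrow(Z) != n) stop("nrow(Z) must equal length(y)", call. = FALSE)
  if (p < 1) stop("Z needs at least one column", call. = FALSE)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  if (thin < 1 || (n_iter - burn_in) < thin) {
    stop("thin must be >= 1 and leave at least one stored draw", call. = FALSE)
  }
  if (!(R2 > 0 && R2 < 1)) stop("R2 must be in (0, 1)", call. = FALSE)

  col_means <- if (center) colMeans(Z) else rep(0, p)
  Zc <- sweep(Z, 2, col_means, "-")
  col_sds <- rep(1, p)
  if (standardize) {
    col_sds <- apply(Zc, 2, stats::sd)
    col_sds[col_sds < 1e-12] <- 1
    Zc <- sweep(Zc, 2, col_sds, "/")
  }

  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-12) vy <- 1
  sum_var_x <- sum(apply(Zc, 2, stats::var))
  if (!is.finite(sum_var_x) || sum_var_x < 1e-12) sum_var_x <- 1

  df_e <- hyper$df_e %||% 5
  df_b <- hyper$df_b %||% 5
  pi0 <- hyper$pi0 %||% 0.5
  p0 <- hyper$p0 %||% 10
  S_e <- hyper$S_e %||% (vy * (1 - R2) * (df_e + 2))
  S_b <- hyper$S_b %||% {
    base <- R2 * vy / sum_var_x * (df_b + 2)
    if (prior %in% c("BayesB", "BayesC")) base / pi0 else base
  }
  lambda2_0 <- 2 * (1 - R2) / R2 * sum_var_x
  lambda_shape <- hyper$lambda_shape %||% 1.1
  lambda_rate <- hyper$lambda_rate %||% ((lambda_shape - 1) / lambda2_0)

  fam_code <- match(prior, c("BRR", "BayesA", "BayesB", "BayesC", "BL")) - 1L
  if (!is.null(seed)) set.seed(seed)
  draws <- gibbs_shrinkage_cpp(
    y, Zc, fam_code, as.integer(n_iter), as.integer(burn_in), as.integer(thin),
    df_e, S_e, df_b, S_b, p0 * pi0, p0 * (1 - pi0),
    lambda_shape, lambda_rate,
    fix$var_e %||% NA_real_, fix$var_b %||% NA_real_,
    fix$pi %||% NA_real_, fix$lambda2 %||% NA_real_)

  theta_scaled <- draws$theta
  # undo column scaling so coefficients refer to the centered, unscaled Z
  if (standardize) theta_scaled <- sweep(theta_scaled, 2, col_sds, "/")
  theta_hat <- colMeans(theta_scaled)

  structure(
    list(prior = prior,
         draws = list(theta = theta_scaled, mu = draws$mu,
                      var_e = draws$var_e, var_b = draws$var_b,
                      pi = draws$pi, lambda2 = draws$lambda2),
         coef = theta_hat,
         intercept = mean(draws$mu),
         var_e = mean(draws$var_e),
         inclusion_prob = draws$inclusion_prob,
         coef_var = draws$coef_var_mean,
         col_means = col_means, col_sds = col_sds,
         center = center, standardize = standardize,
         n = n, p = p, n_save = draws$n_save,
         mcmc = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                     seed = seed),
         R2 = R2,
         hyper = list(df_e = df_e, S_e = S_e, df_b = df_b, S_b = S_b,
                      pi0 = pi0, p0 = p0, lambda_shape = lambda_shape,
                      lambda_rate = lambda_rate)),
    class = "bfr_gibbs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bfr_gibbs <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d, p = %d, %d stored draws; sigma2 = %.4g\n",
              x$prior, x$n, x$p, x$n_save, x$var_e))
  invisible(x)
}

#' Predict responses from a shrinkage fit
#'
#' Posterior-mean prediction `y_hat = mu_hat + Z_new theta_hat`, applying the
#' training-column centering/scaling to `Z_new`.
#'
#' @param object A `bfr_gibbs` fit.
#' @param Z_new Numeric matrix with the same columns as the training design.
#' @param drawwise Return the `n_save x n_new` matrix of draw-wise
#'   predictions instead of the posterior-mean vector.
#' @param ... Unused.
#' @return Numeric vector of predictions (or a matrix when `drawwise`).
#' @export
predict.bfr_gibbs <- function(object, Z_new, drawwise = FALSE, ...) {
  Z_new <- as.matrix(Z_new)
  if (ncol(Z_new) != object$p) {
    stop(sprintf("Z_new has %d columns; the fit used %d",
                 ncol(Z_new), object$p), call. = FALSE)
  }
  Zc <- sweep(Z_new, 2, object$col_means, "-")
  if (drawwise) {
    return(object$draws$mu + object$draws$theta %*% t(Zc))
  }
  drop(object$intercept + Zc %*% object$coef)
}

#' Fit a Bayesian functional regression
#'
#' End-to-end fit: builds the design matrix for the chosen method
#' (see [design_matrix()]) from a functional dataset with response, then runs
#' the shrinkage Gibbs sampler (see [gibbs_shrinkage()]).
#'
#' @param data Curves with response, as accepted by [as_fdata()].
#' @param method One of `"M1"` ... `"M7"`.
#' @param basis `basis_system` matching the method (ignored for M1).
#' @param prior Shrinkage prior family.
#' @param psi,rule,refine Passed to [design_matrix()].
#' @param ... Extra arguments split between [as_fdata()] (`response`, `id`)
#'   and [gibbs_shrinkage()] (`n_iter`, `seed`, ...).
#' @inheritParams gibbs_shrinkage
#' @return A `bfr_fit` holding the posterior (`$posterior`), the design
#'   bundle (`$bundle`) and the training response.
#' @examples
#' \donttest{
#' sim <- simulate_curves(n = 60, m = 80, seed = 1)
#' sim <- simulate_phenotypes(sim, beta = function(t) sin(2 * pi * t / 459),
#'                            seed = 2)
#' b <- basis_bspline(c(392, 851), degree = 3, n_knots = 19)
#' fit <- fit_bfr(sim$data, method = "M6", basis = b, prior = "BRR",
#'                n_iter = 1500, burn_in = 500, seed = 3)
#' }
#' @export
fit_bfr <- function(data, method = "M6", basis = NULL,
                    prior = c("BRR", "BayesA", "BayesB", "BayesC", "BL"),
                    psi = NULL, rule = "grid_sum", refine = 10,
                    response = NULL, id = NULL,
                    n_iter = 6000, burn_in = 1000, thin = 5, seed = NULL,
                    center = TRUE, standardize = FALSE, R2 = 0.5,
                    hyper = list(), fix = list()) {
  prior <- match.arg(prior)
  data <- as_fdata(data, response = response, id = id)
  if (is.null(data$y)) {
    stop("data must carry a response to fit (see `response =`)", call. = FALSE)
  }
  bundle <- design_matrix(data, method = method, basis = basis, psi = psi,
                          rule = rule, refine = refine)
  posterior <- gibbs_shrinkage(data$y, bundle$Z, prior = prior,
                               n_iter = n_iter, burn_in = burn_in, thin = thin,
                               seed = seed, center = center,
                               standardize = standardize, R2 = R2,
                               hyper = hyper, fix = fix)
  structure(list(posterior = posterior, bundle = bundle,
                 y = data$y, ids = data$ids, grid = data$grid),
            class = "bfr_fit")
}

#' @export
print.bfr_fit <- function(x, ...) {
  cat(sprintf("<Bayesian functional regression> method %s, prior %s\n",
              x$bundle$method, x$posterior$prior))
  cat(sprintf("  n = %d curves, design %d x %d, %d stored draws\n",
              length(x$y), nrow(x$bundle$Z), ncol(x$bundle$Z),
              x$posterior$n_save))
  invisible(x)
}

#' @export
predict.bfr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(predict(object$posterior, object$bundle$Z, ...))
  }
  Z_new <- rebuild_design(object$bundle, newdata, ...)
  predict(object$posterior, Z_new)
}

#' Reconstruct the functional coefficient beta(t)
#'
#' For fits whose coefficients live in a basis space (methods M2/M3 via the
#' coefficient-function basis `psi`, M6/M7 via the curve basis itself), the
#' functional coefficient is `beta(t) = sum_s theta_s psi_s(t)`. Draw-wise
#' evaluation yields pointwise credible bands. Fits of M1/M4/M5 carry one
#' coefficient per measurement point instead — use
#' [pointwise_coefficients()] for those.
#'
#' @param fit A `bfr_fit` from method M2, M3, M6 or M7.
#' @param t Evaluation points (default: the training grid).
#' @param level Credible-band level.
#' @return A tibble with columns `t`, `estimate`, `lower`, `upper`.
#' @export
beta_curve <- function(fit, t = NULL, level = 0.95) {
  stopifnot(inherits(fit, "bfr_fit"))
  if (!fit$bundle$method %in% c("M2", "M3", "M6", "M7")) {
    stop(sprintf(
      "beta_curve() requires a basis-coefficient fit (M2/M3/M6/M7); method %s has per-band coefficients, see pointwise_coefficients()",
      fit$bundle$method), call. = FALSE)
  }
  if (is.null(t)) t <- fit$grid
  psi <- fit$bundle$psi
  Psi <- evaluate_basis(psi, t)
  est <- drop(Psi %*% fit$posterior$coef)
  draws <- fit$posterior$draws$theta %*% t(Psi)  # n_save x length(t)
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  tibble::tibble(t = t, estimate = est, lower = qs[1, ], upper = qs[2, ])
}

#' Per-band coefficients for raw/smoothed designs
#'
#' Methods M1, M4 and M5 regress directly on one column per measurement
#' point; their coefficients are returned as-is against the grid.
#'
#' @param fit A `bfr_fit` from method M1, M4 or M5.
#' @return A tibble with columns `t`, `estimate`.
#' @export
pointwise_coefficients <- function(fit) {
  stopifnot(inherits(fit, "bfr_fit"))
  if (!fit$bundle$method %in% c("M1", "M4", "M5")) {
    stop("pointwise_coefficients() applies to M1/M4/M5 fits; use beta_curve()",
         call. = FALSE)
  }
  tibble::tibble(t = fit$grid, estimate = fit$posterior$coef)
}
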