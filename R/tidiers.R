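#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Bayesian functional regression fit
#'
#' One row per model term (intercept, coefficients, residual variance) with
#' posterior mean, standard deviation and central 95% credible interval.
#' BayesB/BayesC fits gain an `inclusion_prob` column.
#'
#' @param x A `bfr_fit` or `bfr_gibbs`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.bfr_gibbs <- function(x, ...) {
  draws <- cbind(x$draws$mu, x$draws$theta, x$draws$var_e)
  terms <- c("(Intercept)", paste0("theta_", seq_len(x$p)), "sigma2")
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  out <- tibble::tibble(
    term = terms,
    estimate = colMeans(draws),
    std.error = apply(draws, 2, stats::sd),
    conf.low = qs[1, ],
    conf.high = qs[2, ])
  if (x$prior %in% c("BayesB", "BayesC")) {
    out$inclusion_prob <- c(NA, x$inclusion_prob, NA)
  }
  out
}

#' @rdname tidy.bfr_gibbs
#' @export
tidy.bfr_fit <- function(x, ...) tidy(x$posterior, ...)

#' Glance at a Bayesian functional regression fit
#'
#' @param x A `bfr_fit` or `bfr_gibbs`.
#' @param ... Unused.
#' @return A one-row tibble: `method` (fits only), `prior`, `n`, `p`,
#'   `n_draws`, `sigma2`, `r_train` (Pearson correlation of fitted vs
#'   observed, fits only).
#' @export
glance.bfr_gibbs <- function(x, ...) {
  tibble::tibble(prior = x$prior, n = x$n, p = x$p, n_draws = x$n_save,
                 sigma2 = x$var_e)
}

#' @rdname glance.bfr_gibbs
#' @export
glance.bfr_fit <- function(x, ...) {
  g <- glance(x$posterior)
  tibble::add_column(g, method = x$bundle$method, .before = 1) |>
    tibble::add_column(r_train = pearson_r(x$y, predict(x)))
}

#' Tidy smoothed curves
#'
#' Long-format basis coefficients: one row per (curve, basis function).
#'
#' @param x A `bfr_smooth`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `basis_index`, `coefficient`.
#' @export
tidy.bfr_smooth <- function(x, ...) {
  L <- n_basis(x$basis)
  tibble::tibble(
    id = rep(x$ids, each = L),
    basis_index = rep(seq_len(L), times = nrow(x$coef)),
    coefficient = as.vector(t(x$coef)))
}

#' @rdname tidy.bfr_smooth
#' @export
glance.bfr_smooth <- function(x, ...) {
  rss <- sum((x$X - x$fitted)^2)
  tibble::tibble(n_curves = nrow(x$coef), m = length(x$grid),
                 L = n_basis(x$basis), family = x$basis$family,
                 rss = rss, mean_residual_sd = mean(x$residual_sd))
}
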