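#' Random balanced cross-validation folds
#'
#' Assigns each of `n` samples to one of `k` folds so that fold sizes differ
#' by at most one, deterministically given `seed`.
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of length `n` with values in `1..k`.
#' @examples
#' table(make_folds(976, 3, seed = 1)) # 326 325 325
#' @export
make_folds <- function(n, k = 3, seed = NULL) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Pearson correlation with contract checks
#'
#' Sample Pearson correlation, erroring (rather than returning `NA`) on
#' length mismatch, fewer than two pairs, non-finite values, or zero variance
#' in either argument.
#'
#' @param a,b Numeric vectors of equal length `>= 2`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("lengths differ", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(a, b)
}

cv_cell_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * index) %% .Machine$integer.max)
}

#' Cross-validated prediction accuracy sweep
#'
#' Reproduces the evaluation protocol used for hyperspectral yield
#' prediction: a k-fold cross-validation (default threefold — two folds to
#' train, one to test) over a grid of methods, priors and basis sizes,
#' scoring each held-out fold by Pearson correlation between observed and
#' predicted responses. Designs for test curves are rebuilt from the
#' training-fold map and centering means only, so no information leaks from
#' the held-out fold. Each cell's sampler seed is derived deterministically
#' from `seed` and the cell index.
#'
#' For B-spline methods the interior-knot count is `L - degree - 1`, so every
#' requested `n_basis` must be at least `degree + 1`. Failures in single
#' cells are recorded (`r = NA` plus a note) without aborting the sweep.
#'
#' @param data Curves with response, as accepted by [as_fdata()].
#' @param methods Character vector among `"M1"` ... `"M7"`.
#' @param priors Character vector of prior families.
#' @param n_basis Integer vector of basis counts `L` to sweep (ignored by M1
#'   cells, which are still reported per `L` like the published tables).
#' @param degree B-spline degree.
#' @param period Fourier period or `"auto"`.
#' @param k,folds Fold count, or an explicit fold-assignment vector.
#' @param seed Base seed for fold assignment and per-cell sampler seeds.
#' @param rule Quadrature rule for M2/M3.
#' @param response,id Column names for data-frame input.
#' @param ... Passed to [gibbs_shrinkage()] (e.g. `n_iter`, `R2`).
#' @return A `bfr_cv` tibble with one row per (method, prior, L, fold):
#'   columns `method`, `prior`, `n_basis`, `degree`, `period`, `fold`, `r`,
#'   `note`. Aggregate with [cv_summary()].
#' @export
run_cv <- function(data, methods = paste0("M", 1:7), priors = "BRR",
                   n_basis = 23, degree = 3, period = "auto", k = 3,
                   folds = NULL, seed = 1, rule = "grid_sum",
                   response = NULL, id = NULL, ...) {
  data <- as_fdata(data, response = response, id = id)
  if (is.null(data$y)) stop("data must carry a response", call. = FALSE)
  n <- nrow(data$X)
  if (is.null(folds)) folds <- make_folds(n, k, seed = seed)
  k <- max(folds)
  domain <- range(data$grid)
  grid_cfg <- tidyr::expand_grid(method = methods, prior = priors,
                                 n_basis = as.integer(n_basis))
  cells <- tidyr::expand_grid(grid_cfg, fold = seq_len(k))
  results <- purrr::pmap_dfr(
    list(cells$method, cells$prior, cells$n_basis, cells$fold,
         seq_len(nrow(cells))),
    function(method, prior, L, fold, idx) {
      fam <- method_family(method)
      out <- tibble::tibble(method = method, prior = prior, n_basis = L,
                            degree = ifelse(fam == "bspline", degree, NA),
                            period = NA_real_, fold = fold, r = NA_real_,
                            note = NA_character_)
      res <- tryCatch({
        basis <- switch(fam,
          none = NULL,
          bspline = basis_bspline(domain, degree = degree, n_knots = L - degree - 1),
          fourier = basis_fourier(domain, n_basis = L, period = period))
        if (fam == "fourier") out$period <- basis$period
        train <- fdata_subset(data, folds != fold)
        test <- fdata_subset(data, folds == fold)
        bundle <- design_matrix(train, method = method, basis = basis,
                                rule = rule)
        post <- suppressWarnings(gibbs_shrinkage(
          train$y, bundle$Z, prior = prior,
          seed = cv_cell_seed(seed, idx), ...))
        y_hat <- predict(post, rebuild_design(bundle, test))
        pearson_r(test$y, y_hat)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("cell %s/%s/L=%d fold %d failed: %s",
                        method, prior, L, fold, conditionMessage(res)),
                call. = FALSE)
        out$note <- conditionMessage(res)
      } else {
        out$r <- res
      }
      out
    })
  structure(results, class = c("bfr_cv", class(results)),
            folds = folds, seed = seed)
}

#' Aggregate a cross-validation sweep
#'
#' Fold-level correlations are averaged per configuration and reported with
#' their standard error `sd(r) / sqrt(k)`, the convention of the published
#' accuracy tables. Cells that failed (`NA`) are dropped with a warning.
#'
#' @param cv A `bfr_cv` tibble from [run_cv()].
#' @return A tibble with columns `method`, `prior`, `n_basis`, `degree`,
#'   `period`, `mean_r`, `se_r`, `n_folds`.
#' @export
cv_summary <- function(cv) {
  stopifnot(inherits(cv, "bfr_cv") || is.data.frame(cv))
  if (anyNA(cv$r)) {
    warning("dropping failed cells from the aggregate", call. = FALSE)
  }
  cv |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$method, .data$prior, .data$n_basis, .data$degree,
                    .data$period) |>
    dplyr::summarise(
      mean_r = mean(.data$r),
      se_r = stats::sd(.data$r) / sqrt(dplyr::n()),
      n_folds = dplyr::n(),
      .groups = "drop")
}
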