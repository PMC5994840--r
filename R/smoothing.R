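#' Smooth curves by least-squares basis projection
#'
#' Fits each observed curve with the shared basis by ordinary least squares:
#' the coefficient vector of curve `i` is `c_i = (Phi' Phi)^{-1} Phi' x_i`,
#' i.e. the raw values multiplied by the smoother ("hat") matrix. The solve is
#' carried out through a QR factorisation of `Phi` for numerical stability;
#' it is algebraically identical to the normal-equations form whenever
#' `Phi' Phi` is well conditioned.
#'
#' @param data A band-table data frame, matrix + grid, or [fdata()] object.
#' @param basis A `basis_system` with `L <= m`.
#' @param ... Passed to [as_fdata()].
#' @return A `bfr_smooth` object: `coef` (`n x L` coefficients), `fitted`
#'   (`n x m` reconstructed smooth curves), `residual_sd` (per-curve estimate
#'   of the measurement-noise standard deviation, with `m - L` degrees of
#'   freedom), plus the basis and grid.
#' @examples
#' sim <- simulate_sine(100, seed = 1)
#' b <- basis_bspline(range(sim$t), degree = 3, n_knots = 7)
#' fit <- smooth_curves(matrix(sim$x, 1), grid = sim$t, basis = b)
#' @export
smooth_curves <- function(data, basis, ...) {
  data <- as_fdata(data, ...)
  stopifnot(inherits(basis, "basis_system"))
  m <- length(data$grid)
  L <- n_basis(basis)
  if (L > m) {
    stop(sprintf("basis size L = %d exceeds grid size m = %d", L, m),
         call. = FALSE)
  }
  Phi <- evaluate_basis(basis, data$grid)
  sv <- svd(Phi, nu = 0, nv = 0)$d
  if (sv[L] < sv[1] * 1e-10) {
    stop(sprintf(
      "rank-deficient basis matrix (%s, L = %d, m = %d): the configuration is unidentifiable on this grid",
      basis$family, L, m), call. = FALSE)
  }
  qr_Phi <- qr(Phi)
  C_hat <- t(qr.coef(qr_Phi, t(data$X)))   # n x L
  fitted <- C_hat %*% t(Phi)               # n x m
  resid <- data$X - fitted
  df <- max(m - L, 1)
  residual_sd <- sqrt(rowSums(resid^2) / df)
  structure(
    list(basis = basis, grid = data$grid, coef = unname(C_hat),
         fitted = unname(fitted), residual_sd = unname(residual_sd),
         X = data$X, ids = data$ids),
    class = "bfr_smooth")
}

#' @export
print.bfr_smooth <- function(x, ...) {
  cat(sprintf("<smoothed curves> %d curves, %s basis L = %d, median residual sd %.4g\n",
              nrow(x$coef), x$basis$family, n_basis(x$basis),
              stats::median(x$residual_sd)))
  invisible(x)
}

#' Select the number of interior knots by GCV or R-squared
#'
#' Scores a set of candidate interior-knot counts for a B-spline smoother and
#' picks one. `gcv` minimises the generalized cross-validation score
#' `GCV(K) = (RSS/N) / (1 - L/m)^2` with `L = q + 1 + K`; `r2` picks the
#' smallest candidate whose coefficient of determination reaches
#' `r2_threshold`. When `data` holds several curves the residual and total
#' sums of squares are accumulated over all curves (a single shared basis is
#' selected for the whole dataset). Ties break toward the smaller candidate;
#' the full score table is returned for audit.
#'
#' @param data Curves as accepted by [as_fdata()] (a single curve may be given
#'   as a 1-row matrix).
#' @param degree B-spline degree, default cubic.
#' @param candidates Integer vector of candidate `K` values.
#' @param criterion `"gcv"` or `"r2"`.
#' @param r2_threshold Target R-squared for the `"r2"` criterion.
#' @param knot_method Passed to [basis_bspline()].
#' @param ... Passed to [as_fdata()].
#' @return A list of class `knot_selection`: `K` (chosen count), `criterion`,
#'   and `scores`, a tibble with one row per candidate (`K`, `L`, `rss`,
#'   `gcv`, `r2`).
#' @export
select_knots <- function(data, degree = 3, candidates,
                         criterion = c("gcv", "r2"), r2_threshold = 0.99,
                         knot_method = "uniform", ...) {
  criterion <- match.arg(criterion)
  data <- as_fdata(data, ...)
  if (!length(candidates)) {
    stop("candidates must be a non-empty vector of knot counts", call. = FALSE)
  }
  candidates <- sort(unique(as.integer(candidates)))
  m <- length(data$grid)
  bad <- candidates[degree + 1 + candidates > m]
  if (length(bad)) {
    stop(sprintf("candidate K = %d gives L > m = %d", bad[1], m), call. = FALSE)
  }
  n <- nrow(data$X)
  N <- n * m
  tss <- sum((data$X - rowMeans(data$X))^2)
  scores <- purrr::map_dfr(candidates, function(K) {
    basis <- basis_bspline(range(data$grid), degree = degree, n_knots = K,
                           knot_method = knot_method, grid = data$grid)
    sm <- smooth_curves(data, basis)
    rss <- sum((data$X - sm$fitted)^2)
    L <- n_basis(basis)
    tibble::tibble(K = K, L = L, rss = rss,
                   gcv = (rss / N) / (1 - L / m)^2,
                   r2 = 1 - rss / tss)
  })
  K <- if (criterion == "gcv") {
    scores$K[which.min(scores$gcv)]
  } else {
    ok <- which(scores$r2 >= r2_threshold)
    if (length(ok)) {
      scores$K[ok[1]]
    } else {
      warning(sprintf(
        "no candidate reaches r2 >= %g; returning the largest (K = %d)",
        r2_threshold, max(candidates)), call. = FALSE)
      max(candidates)
    }
  }
  structure(list(K = K, criterion = criterion, r2_threshold = r2_threshold,
                 degree = degree, scores = scores),
            class = "knot_selection")
}

#' @export
print.knot_selection <- function(x, ...) {
  cat(sprintf("<knot selection> criterion %s -> K = %d (degree %d)\n",
              x$criterion, x$K, x$degree))
  print(x$scores)
  invisible(x)
}
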