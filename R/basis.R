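#' Validate a measurement grid
#'
#' A measurement grid is the ordered set of points of the continuum (wavelength
#' in nm, time, ...) at which every curve is observed. It must be strictly
#' increasing with at least two points; duplicated points are rejected because
#' they would duplicate rows of the basis matrix and silently over-weight them
#' in the least-squares smoother.
#'
#' @param points Numeric vector of measurement points.
#' @return The validated grid, invisibly usable downstream.
#' @keywords internal
validate_grid <- function(points) {
  if (!is.numeric(points) || length(points) < 2) {
    stop("grid must be a numeric vector with at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(points))) {
    stop("grid contains non-finite points", call. = FALSE)
  }
  if (any(diff(points) <= 0)) {
    stop("grid points must be strictly increasing (no duplicates)", call. = FALSE)
  }
  invisible(points)
}

#' Place interior knots on a domain
#'
#' Interior knots for a B-spline system can be placed equally spaced inside the
#' domain (`uniform`) or at empirical quantiles of the observed measurement
#' points (`quantile`), the latter concentrating flexibility where measurements
#' are dense. Quantile probabilities are `k/(K+1)` for `k = 1..K`, with
#' linear-interpolation (type 7) empirical quantiles, so the two methods
#' coincide on an equispaced grid.
#'
#' @param grid Numeric vector of measurement points (used by the quantile
#'   method; also supplies the default domain).
#' @param K Number of interior knots (non-negative integer).
#' @param method `"uniform"` or `"quantile"`.
#' @param domain Length-2 numeric, the `[lo, hi]` bounds. Defaults to the grid
#'   range.
#' @return Numeric vector of `K` non-decreasing knots strictly inside the
#'   domain.
#' @examples
#' place_knots(seq(0, 1, length.out = 101), K = 3, method = "uniform")
#' @export
place_knots <- function(grid, K, method = c("uniform", "quantile"),
                        domain = range(grid)) {
  method <- match.arg(method)
  validate_grid(grid)
  if (!is.numeric(K) || length(K) != 1 || K < 0 || K != round(K)) {
    stop("K must be a single non-negative integer", call. = FALSE)
  }
  lo <- domain[1]; hi <- domain[2]
  if (!(lo < hi)) stop("domain must satisfy lo < hi", call. = FALSE)
  if (K == 0) return(numeric(0))
  knots <- switch(method,
    uniform = lo + seq_len(K) * (hi - lo) / (K + 1),
    quantile = stats::quantile(grid, probs = seq_len(K) / (K + 1),
                               names = FALSE, type = 7)
  )
  if (any(knots <= lo) || any(knots >= hi)) {
    stop("knot placement produced knots on or outside the domain boundary; ",
         "reduce K or use a different method", call. = FALSE)
  }
  knots
}

#' Construct a B-spline basis system
#'
#' Builds a clamped (open uniform) B-spline system of polynomial degree `q`
#' with `K` interior knots, hence `L = q + 1 + K` basis functions. Boundary
#' knots sit at the domain endpoints with multiplicity `q + 1`, which
#' guarantees the partition-of-unity property and that the span interpolates
#' at the endpoints.
#'
#' @param domain Length-2 numeric `[lo, hi]`.
#' @param degree Polynomial degree `q >= 1` (1 linear, 2 quadratic, 3 cubic).
#' @param n_knots Number of interior knots `K >= 0`. Ignored when `knots` is
#'   supplied.
#' @param knot_method Knot placement rule, see [place_knots()].
#' @param grid Measurement points, required for `knot_method = "quantile"`.
#' @param knots Optional explicit interior knots (non-decreasing, strictly
#'   inside the domain); overrides `n_knots`/`knot_method`.
#' @return A `basis_system` object of family `"bspline"`.
#' @examples
#' b <- basis_bspline(c(392, 851), degree = 3, n_knots = 19)
#' n_basis(b) # 23
#' @export
basis_bspline <- function(domain, degree = 3, n_knots = 0,
                          knot_method = c("uniform", "quantile"),
                          grid = NULL, knots = NULL) {
  knot_method <- match.arg(knot_method)
  lo <- domain[1]; hi <- domain[2]
  if (!is.numeric(domain) || length(domain) != 2 || !(lo < hi)) {
    stop("domain must be numeric of length 2 with lo < hi", call. = FALSE)
  }
  if (!is.numeric(degree) || length(degree) != 1 || degree < 1 ||
      degree != round(degree)) {
    stop("degree must be an integer >= 1", call. = FALSE)
  }
  if (is.null(knots)) {
    if (knot_method == "quantile") {
      if (is.null(grid)) {
        stop("quantile knot placement requires `grid`", call. = FALSE)
      }
      knots <- place_knots(grid, n_knots, "quantile", domain = domain)
    } else {
      ref <- if (is.null(grid)) c(lo, hi) else grid
      knots <- place_knots(ref, n_knots, "uniform", domain = domain)
    }
  } else {
    knots <- as.numeric(knots)
    if (any(diff(knots) < 0)) stop("knots must be non-decreasing", call. = FALSE)
    if (length(knots) && (any(knots <= lo) || any(knots >= hi))) {
      stop("interior knots must lie strictly inside the domain", call. = FALSE)
    }
  }
  structure(
    list(family = "bspline", degree = as.integer(degree), knots = knots,
         domain = c(lo, hi), L = as.integer(degree + 1 + length(knots))),
    class = c("bspline_basis", "basis_system")
  )
}

#' Construct a Fourier basis system
#'
#' The basis is the constant function followed by sine/cosine pairs of
#' increasing frequency: `1, sin(2*pi*t/T), cos(2*pi*t/T), sin(4*pi*t/T), ...`.
#' An even `L` truncates the sequence after the final sine (with a warning),
#' since a complete system has odd length. The default period is the domain
#' width `hi - lo`, the conventional choice when no cyclic structure is known.
#'
#' @param domain Length-2 numeric `[lo, hi]`.
#' @param n_basis Number of basis functions `L >= 1`.
#' @param period Positive period `T`, or `"auto"` for `hi - lo`.
#' @return A `basis_system` object of family `"fourier"`.
#' @examples
#' basis_fourier(c(392, 851), n_basis = 23) # period resolves to 459
#' @export
basis_fourier <- function(domain, n_basis, period = "auto") {
  lo <- domain[1]; hi <- domain[2]
  if (!is.numeric(domain) || length(domain) != 2 || !(lo < hi)) {
    stop("domain must be numeric of length 2 with lo < hi", call. = FALSE)
  }
  if (!is.numeric(n_basis) || length(n_basis) != 1 || n_basis < 1 ||
      n_basis != round(n_basis)) {
    stop("n_basis must be an integer >= 1", call. = FALSE)
  }
  if (identical(period, "auto")) period <- hi - lo
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) ||
      period <= 0) {
    stop("period must be a positive number or \"auto\"", call. = FALSE)
  }
  if (n_basis %% 2 == 0 && n_basis > 1) {
    warning("even n_basis truncates the Fourier system after the final sine",
            call. = FALSE)
  }
  structure(
    list(family = "fourier", period = period, domain = c(lo, hi),
         L = as.integer(n_basis)),
    class = c("fourier_basis", "basis_system")
  )
}

#' Number of basis functions of a system
#' @param basis A `basis_system`.
#' @return Integer `L`.
#' @export
n_basis <- function(basis) {
  stopifnot(inherits(basis, "basis_system"))
  basis$L
}

#' Evaluate a basis system on a set of points
#'
#' Returns the `m x L` basis matrix with entry `[j, l] = phi_l(t_j)`. B-spline
#' systems require all points inside their domain; Fourier systems evaluate
#' anywhere.
#'
#' @param basis A `basis_system`.
#' @param t Numeric vector of evaluation points.
#' @return Numeric matrix of dimension `length(t) x n_basis(basis)`.
#' @export
evaluate_basis <- function(basis, t) UseMethod("evaluate_basis")

#' @export
evaluate_basis.bspline_basis <- function(basis, t) {
  if (!is.numeric(t) || !length(t) || any(!is.finite(t))) {
    stop("evaluation points must be finite numerics", call. = FALSE)
  }
  lo <- basis$domain[1]; hi <- basis$domain[2]
  if (any(t < lo) || any(t > hi)) {
    stop(sprintf("B-spline evaluation outside domain [%g, %g]", lo, hi),
         call. = FALSE)
  }
  q <- basis$degree
  all_knots <- c(rep(lo, q + 1), basis$knots, rep(hi, q + 1))
  Phi <- splines::splineDesign(all_knots, t, ord = q + 1)
  dimnames(Phi) <- NULL
  Phi
}

#' @export
evaluate_basis.fourier_basis <- function(basis, t) {
  if (!is.numeric(t) || !length(t) || any(!is.finite(t))) {
    stop("evaluation points must be finite numerics", call. = FALSE)
  }
  L <- basis$L
  Tp <- basis$period
  n_pairs <- ceiling((L - 1) / 2)
  Phi <- matrix(1, nrow = length(t), ncol = L)
  if (n_pairs > 0) {
    for (r in seq_len(n_pairs)) {
      ang <- 2 * pi * r * t / Tp
      s_col <- 2 * r
      Phi[, s_col] <- sin(ang)
      c_col <- 2 * r + 1
      if (c_col <= L) Phi[, c_col] <- cos(ang)
    }
  }
  Phi
}

#' @export
print.basis_system <- function(x, ...) {
  if (x$family == "bspline") {
    cat(sprintf(
      "<B-spline basis> degree %d, %d interior knots, L = %d on [%g, %g]\n",
      x$degree, length(x$knots), x$L, x$domain[1], x$domain[2]))
  } else {
    cat(sprintf("<Fourier basis> L = %d, period %g on [%g, %g]\n",
                x$L, x$period, x$domain[1], x$domain[2]))
  }
  invisible(x)
}
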