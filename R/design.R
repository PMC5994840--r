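#' Cross-basis integral matrix
#'
#' Computes `J[l, s] = integral of phi_l(t) psi_s(t) dt`, the matrix linking
#' the curve basis `phi` to the coefficient-function basis `psi`. Two
#' quadrature conventions are supported:
#'
#' * `grid_sum` — the plain sum `sum_j phi_l(t_j) psi_s(t_j)` over the raw
#'   grid (no `dt` factor), which makes `J = Phi' Psi` exactly. This is the
#'   default: with identical bases it renders the integral design `W`
#'   identical to the reduced design `X Phi`, and least-squares or shrinkage
#'   fits are invariant to the missing physical scale (it is absorbed by the
#'   coefficients).
#' * `trapezoid` — composite trapezoid rule on the grid refined `refine`-fold
#'   within each interval, carrying physical `dt` units.
#'
#' @param phi,psi `basis_system` objects sharing the grid's domain.
#' @param grid Measurement grid.
#' @param rule `"grid_sum"` or `"trapezoid"`.
#' @param refine Subdivision factor per grid interval for the trapezoid rule.
#' @return A `cross_integral` object with elements `J` (`L x S` matrix),
#'   `rule`, `phi`, `psi`.
#' @export
cross_integral <- function(phi, psi = phi, grid,
                           rule = c("grid_sum", "trapezoid"), refine = 10) {
  rule <- match.arg(rule)
  stopifnot(inherits(phi, "basis_system"), inherits(psi, "basis_system"))
  validate_grid(grid)
  if (max(abs(phi$domain - psi$domain)) > 1e-8 * max(1, abs(phi$domain[2]))) {
    stop("phi and psi must share the same domain", call. = FALSE)
  }
  if (rule == "grid_sum") {
    Phi <- evaluate_basis(phi, grid)
    # one-argument crossprod keeps J exactly symmetric for identical systems
    J <- if (identical(phi, psi)) crossprod(Phi)
         else crossprod(Phi, evaluate_basis(psi, grid))
  } else {
    m <- length(grid)
    fine <- unlist(lapply(seq_len(m - 1), function(j) {
      seq(grid[j], grid[j + 1], length.out = refine + 1)[-(refine + 1)]
    }))
    fine <- c(fine, grid[m])
    d <- diff(fine)
    w <- c(d / 2, 0) + c(0, d / 2)  # trapezoid weights
    Pf <- evaluate_basis(phi, fine)
    Qf <- evaluate_basis(psi, fine)
    J <- crossprod(Pf * w, Qf)
  }
  structure(list(J = unname(J), rule = rule, refine = refine,
                 phi = phi, psi = psi),
            class = "cross_integral")
}

method_family <- function(method) {
  switch(method,
    M1 = "none",
    M2 = , M4 = , M6 = "bspline",
    M3 = , M5 = , M7 = "fourier",
    stop(sprintf("unknown method '%s'", method), call. = FALSE))
}

#' Build a regression design matrix for one of the seven methods
#'
#' Constructs the design matrix `Z` that carries the curve information into
#' the linear model `y = mu + Z theta + e`, under one of seven methods:
#'
#' | method | design | basis | columns |
#' |--------|--------|-------|---------|
#' | M1 | raw band matrix `X` | none | `m` |
#' | M2 | `W = X Phi (Phi'Phi)^{-1} J` | B-spline | `S` |
#' | M3 | `W` | Fourier | `S` |
#' | M4 | smoothed `X* = X Phi (Phi'Phi)^{-1} Phi'` | B-spline | `m` |
#' | M5 | `X*` | Fourier | `m` |
#' | M6 | reduced `X** = X Phi` | B-spline | `L` |
#' | M7 | `X**` | Fourier | `L` |
#'
#' Every method is a fixed linear map of the rows of `X` (`Z = X M`), so the
#' identical map rebuilds the design for new samples — see
#' [rebuild_design()]. The coefficient-function basis `psi` defaults to `phi`
#' with `S = L`.
#'
#' @param data Curves as accepted by [as_fdata()].
#' @param method One of `"M1"` ... `"M7"`.
#' @param basis A `basis_system` whose family matches the method (B-spline for
#'   M2/M4/M6, Fourier for M3/M5/M7); ignored for M1.
#' @param psi Optional coefficient-function basis for M2/M3 (default `basis`).
#' @param rule Quadrature rule for the cross integral (M2/M3 only).
#' @param refine Trapezoid refinement factor (M2/M3 only).
#' @param ... Passed to [as_fdata()].
#' @return A `design_bundle`: `method`, `Z` (`n x p`), the linear `map`
#'   (`m x p`, `NULL` for M1), basis metadata and the cross integral (M2/M3).
#' @export
design_matrix <- function(data, method, basis = NULL, psi = NULL,
                          rule = c("grid_sum", "trapezoid"), refine = 10, ...) {
  rule <- match.arg(rule)
  data <- as_fdata(data, ...)
  method <- match.arg(method, paste0("M", 1:7))
  fam <- method_family(method)
  m <- length(data$grid)
  if (fam == "none") {
    if (!is.null(basis)) {
      warning("M1 uses the raw band matrix; `basis` is ignored", call. = FALSE)
    }
    return(structure(
      list(method = method, Z = data$X, map = NULL, phi = NULL, psi = NULL,
           J = NULL, rule = NULL, grid = data$grid, ids = data$ids),
      class = "design_bundle"))
  }
  if (is.null(basis) || !inherits(basis, "basis_system")) {
    stop(sprintf("method %s requires a basis_system", method), call. = FALSE)
  }
  if (basis$family != fam) {
    stop(sprintf("method %s requires a %s basis, got %s",
                 method, fam, basis$family), call. = FALSE)
  }
  L <- n_basis(basis)
  if (L > m) {
    stop(sprintf("basis size L = %d exceeds grid size m = %d", L, m),
         call. = FALSE)
  }
  Phi <- evaluate_basis(basis, data$grid)
  PtP <- crossprod(Phi)
  kap <- tryCatch(kappa(PtP, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e12) {
    stop(sprintf(
      "ill-conditioned Phi'Phi (%s basis, L = %d, m = %d): cannot form the smoother",
      basis$family, L, m), call. = FALSE)
  }
  J_obj <- NULL
  map <- switch(method,
    M2 = , M3 = {
      if (is.null(psi)) psi <- basis
      J_obj <- cross_integral(basis, psi, data$grid, rule = rule,
                              refine = refine)
      if (rule == "grid_sum" && identical(psi, basis)) {
        # J = Phi'Phi, so Phi (Phi'Phi)^{-1} J collapses to Phi exactly
        Phi
      } else {
        Phi %*% solve(PtP, J_obj$J)
      }
    },
    M4 = , M5 = Phi %*% solve(PtP, t(Phi)),
    M6 = , M7 = Phi
  )
  structure(
    list(method = method, Z = data$X %*% map, map = map, phi = basis,
         psi = if (method %in% c("M2", "M3")) psi else
               if (method %in% c("M6", "M7")) basis else NULL,
         J = if (is.null(J_obj)) NULL else J_obj$J,
         rule = if (is.null(J_obj)) NULL else J_obj$rule,
         grid = data$grid, ids = data$ids),
    class = "design_bundle")
}

#' Rebuild a design matrix for new curves
#'
#' Applies the linear map learned at construction time to held-out curves
#' measured on the same grid, guaranteeing that train and test designs live in
#' the same coordinates (no refitting, no leakage).
#'
#' @param bundle A `design_bundle`.
#' @param newdata New curves as accepted by [as_fdata()] on the same grid.
#' @param ... Passed to [as_fdata()].
#' @return Numeric `n_new x p` design matrix.
#' @export
rebuild_design <- function(bundle, newdata, ...) {
  stopifnot(inherits(bundle, "design_bundle"))
  newdata <- as_fdata(newdata, ...)
  if (length(newdata$grid) != length(bundle$grid) ||
      max(abs(newdata$grid - bundle$grid)) > 1e-8) {
    stop("new curves must be measured on the training grid", call. = FALSE)
  }
  if (is.null(bundle$map)) newdata$X else newdata$X %*% bundle$map
}

#' @export
print.design_bundle <- function(x, ...) {
  cat(sprintf("<design bundle> method %s: %d x %d%s\n",
              x$method, nrow(x$Z), ncol(x$Z),
              if (is.null(x$phi)) " (raw bands)"
              else sprintf(" (%s basis, L = %d)", x$phi$family, n_basis(x$phi))))
  invisible(x)
}
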