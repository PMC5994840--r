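#' Plot smoothed curves against the raw observations
#'
#' Raw measurements as points (for small datasets) or thin lines, with the
#' reconstructed smooth curves overlaid.
#'
#' @param object A `bfr_smooth`.
#' @param max_curves Plot at most this many curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bfr_smooth <- function(object, max_curves = 20, ...) {
  keep <- seq_len(min(nrow(object$coef), max_curves))
  long <- tibble::tibble(
    id = rep(object$ids[keep], each = length(object$grid)),
    t = rep(object$grid, times = length(keep)),
    observed = as.vector(t(object$X[keep, , drop = FALSE])),
    smoothed = as.vector(t(object$fitted[keep, , drop = FALSE])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, group = .data$id)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        alpha = 0.25, size = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed, colour = .data$id),
                       linewidth = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = "measurement point", y = "value",
                  title = sprintf("Least-squares smoothing (%s basis, L = %d)",
                                  object$basis$family, n_basis(object$basis)))
}

#' Plot the estimated coefficient function
#'
#' For basis-coefficient fits (M2/M3/M6/M7): the posterior-mean `beta(t)` with
#' its pointwise credible band. For per-band fits (M1/M4/M5): the coefficient
#' profile across the grid.
#'
#' @param object A `bfr_fit`.
#' @param level Credible level for the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bfr_fit <- function(object, level = 0.95, ...) {
  if (object$bundle$method %in% c("M2", "M3", "M6", "M7")) {
    bc <- beta_curve(object, level = level)
    ggplot2::ggplot(bc, ggplot2::aes(x = .data$t, y = .data$estimate)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           fill = "steelblue", alpha = 0.25) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::labs(x = "measurement point", y = expression(hat(beta)(t)),
                    title = sprintf("Coefficient function (%s, %s)",
                                    object$bundle$method,
                                    object$posterior$prior))
  } else {
    pc <- pointwise_coefficients(object)
    ggplot2::ggplot(pc, ggplot2::aes(x = .data$t, y = .data$estimate)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::labs(x = "measurement point", y = "coefficient",
                    title = sprintf("Per-band coefficients (%s, %s)",
                                    object$bundle$method,
                                    object$posterior$prior))
  }
}

#' Plot a cross-validation sweep
#'
#' Mean Pearson correlation (with SE error bars) against the number of basis
#' functions, one line per method, faceted by prior when several priors were
#' swept.
#'
#' @param object A `bfr_cv` from [run_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bfr_cv <- function(object, ...) {
  agg <- suppressWarnings(cv_summary(object))
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$n_basis, y = .data$mean_r,
                                         colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_r - .data$se_r, ymax = .data$mean_r + .data$se_r),
      size = 0.2) +
    ggplot2::labs(x = "number of basis functions (L)",
                  y = "mean Pearson correlation",
                  title = "Cross-validated prediction accuracy")
  if (length(unique(agg$prior)) > 1) {
    p <- p + ggplot2::facet_wrap(~prior)
  }
  p
}

#' Plot knot-selection scores
#'
#' @param object A `knot_selection` from [select_knots()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.knot_selection <- function(object, ...) {
  crit <- object$criterion
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$K, y = .data[[crit]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$K, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "interior knots (K)", y = toupper(crit),
                  title = sprintf("Knot selection by %s", toupper(crit)))
}
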