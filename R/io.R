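#' Read a band table from CSV
#'
#' A band table has one optional identifier column, one optional response
#' column (e.g. grain yield), and band columns whose headers are the numeric
#' measurement points (e.g. wavelengths `392 ... 851`). Headers must parse to
#' a strictly increasing grid; missing cells in used columns are an error
#' naming the offending row and column.
#'
#' @param path CSV file path.
#' @param response Name of the response column, if any.
#' @param id Name of the identifier column, if any.
#' @return An [fdata()] object.
#' @export
read_band_table <- function(path, response = NULL, id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  # base read.csv parses doubles through strtod, which is correctly rounded,
  # so full-precision writes round-trip bitwise
  df <- utils::read.csv(path, check.names = FALSE)
  as_fdata(df, response = response, id = id)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a band table to CSV at full precision
#'
#' Numeric cells are written with 17 significant digits so a write-then-read
#' round trip reproduces the doubles bitwise.
#'
#' @param data An [fdata()] (or anything [as_fdata()] accepts), or a
#'   `bfr_sim`.
#' @param path Output CSV path.
#' @param response Column name used for the response, when present.
#' @param ... Passed to [as_fdata()].
#' @return `path`, invisibly.
#' @export
write_band_table <- function(data, path, response = "y", ...) {
  if (inherits(data, "bfr_sim")) data <- data$data
  data <- as_fdata(data, ...)
  out <- data.frame(id = data$ids, stringsAsFactors = FALSE)
  if (!is.null(data$y)) out[[response]] <- fmt_num(data$y)
  bands <- as.data.frame(apply(data$X, 2, fmt_num),
                         stringsAsFactors = FALSE)
  if (nrow(data$X) == 1) bands <- as.data.frame(t(bands))
  names(bands) <- as.character(data$grid)
  readr::write_csv(cbind(out, bands), path, progress = FALSE)
  invisible(path)
}

#' Write the truth sidecar of a simulation
#'
#' Companion CSV for test harnesses: the noise-free truth curves (and the
#' coefficient function and signal when phenotypes were simulated).
#'
#' @param sim A `bfr_sim`.
#' @param path Output CSV path for the truth curves.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(sim, path) {
  stopifnot(inherits(sim, "bfr_sim"))
  truth_fd <- fdata(sim$truth$curves, sim$data$grid,
                    y = sim$truth$signal, ids = sim$data$ids)
  write_band_table(truth_fd, path,
                   response = if (is.null(sim$truth$signal)) "y" else "signal")
  invisible(path)
}

#' Write fit outputs and a reproducibility manifest
#'
#' Writes `predictions.csv` (id, observed, predicted),
#' `posterior_summary.csv` (term, estimate, sd, 2.5/97.5% quantiles),
#' `beta_curve.csv` (for basis-coefficient methods) and `manifest.json`
#' recording the configuration, seed and package version. Re-running the same
#' configuration and seed reproduces every numeric output bitwise.
#'
#' @param fit A `bfr_fit`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "bfr_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  preds <- tibble::tibble(id = fit$ids, observed = fit$y,
                          predicted = predict(fit))
  readr::write_csv(preds, file.path(dir, "predictions.csv"), progress = FALSE)
  readr::write_csv(tidy(fit), file.path(dir, "posterior_summary.csv"),
                   progress = FALSE)
  if (fit$bundle$method %in% c("M2", "M3", "M6", "M7")) {
    readr::write_csv(beta_curve(fit), file.path(dir, "beta_curve.csv"),
                     progress = FALSE)
  }
  write_manifest(fit_config(fit), file.path(dir, "manifest.json"))
  invisible(dir)
}

fit_config <- function(fit) {
  b <- fit$bundle
  post <- fit$posterior
  cfg <- list(method = b$method, prior = post$prior,
              n = post$n, p = post$p,
              center = post$center, standardize = post$standardize,
              R2 = post$R2, mcmc = post$mcmc, hyper = post$hyper)
  if (!is.null(b$phi)) {
    cfg$basis <- list(family = b$phi$family, L = n_basis(b$phi),
                      degree = b$phi$degree, period = b$phi$period,
                      knots = b$phi$knots, domain = b$phi$domain)
    cfg$rule <- b$rule
  }
  cfg
}

#' Write cross-validation outputs
#'
#' Writes `cv_folds.csv` (one row per method/prior/L/fold cell),
#' `cv_summary.csv` (mean and SE per configuration) and `manifest.json`.
#'
#' @param cv A `bfr_cv` from [run_cv()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cv_outputs <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(cv), file.path(dir, "cv_folds.csv"),
                   progress = FALSE)
  readr::write_csv(suppressWarnings(cv_summary(cv)),
                   file.path(dir, "cv_summary.csv"), progress = FALSE)
  write_manifest(list(kind = "cv", seed = attr(cv, "seed"),
                      k = max(attr(cv, "folds"))),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}

write_manifest <- function(config, path) {
  config$software <- list(
    package = "bfr",
    version = as.character(utils::packageVersion("bfr")),
    r_version = as.character(getRversion()))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
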