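#' Assemble a functional dataset
#'
#' A functional dataset holds the shared measurement grid (length `m`), the
#' `n x m` matrix of observed curve values, an optional length-`n` scalar
#' response (the trait to predict), and optional sample identifiers.
#'
#' @param X Numeric `n x m` matrix, one curve per row.
#' @param grid Numeric vector of `m` strictly increasing measurement points.
#' @param y Optional numeric length-`n` response.
#' @param ids Optional character sample identifiers.
#' @return An object of class `fdata`.
#' @export
fdata <- function(X, grid, y = NULL, ids = NULL) {
  X <- as.matrix(X)
  validate_grid(grid)
  if (ncol(X) != length(grid)) {
    stop("ncol(X) must equal length(grid)", call. = FALSE)
  }
  if (nrow(X) < 1) stop("X needs at least one row", call. = FALSE)
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
    if (any(!is.finite(y))) stop("y contains non-finite values", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  structure(list(grid = as.numeric(grid), X = unname(X), y = y,
                 ids = as.character(ids)),
            class = "fdata")
}

#' Coerce to a functional dataset
#'
#' Band tables (data frames whose numeric-named columns are the measurement
#' grid, e.g. wavelengths `392 ... 851`) are parsed into an [fdata()] object;
#' matrices need an explicit `grid`; `fdata` objects pass through.
#'
#' @param x A data frame band table, a numeric matrix, or an `fdata`.
#' @param response Name of the response column (data frames only).
#' @param id Name of the identifier column (data frames only). When `NULL`,
#'   any single non-numeric-named, non-response column is used.
#' @param grid Measurement grid (matrices only).
#' @param ... Unused.
#' @return An `fdata` object.
#' @export
as_fdata <- function(x, ...) UseMethod("as_fdata")

#' @rdname as_fdata
#' @export
as_fdata.fdata <- function(x, ...) x

#' @rdname as_fdata
#' @export
as_fdata.matrix <- function(x, grid, y = NULL, ids = NULL, ...) {
  fdata(x, grid, y = y, ids = ids)
}

#' @rdname as_fdata
#' @export
as_fdata.data.frame <- function(x, response = NULL, id = NULL, ...) {
  nms <- names(x)
  band_vals <- suppressWarnings(as.numeric(nms))
  is_band <- !is.na(band_vals)
  if (!is.null(response)) {
    if (!response %in% nms) {
      stop(sprintf("response column '%s' not found", response), call. = FALSE)
    }
    is_band[nms == response] <- FALSE
  }
  if (!is.null(id)) {
    if (!id %in% nms) {
      stop(sprintf("id column '%s' not found", id), call. = FALSE)
    }
    is_band[nms == id] <- FALSE
  }
  if (sum(is_band) < 2) {
    stop("band table needs at least 2 numeric-named band columns", call. = FALSE)
  }
  grid <- band_vals[is_band]
  if (any(diff(grid) <= 0)) {
    stop("band column headers must form a strictly increasing numeric grid",
         call. = FALSE)
  }
  band_cols <- x[is_band]
  for (j in seq_along(band_cols)) {
    col <- band_cols[[j]]
    if (!is.numeric(col)) {
      stop(sprintf("band column '%s' is not numeric", nms[is_band][j]),
           call. = FALSE)
    }
    if (any(is.na(col))) {
      stop(sprintf("missing value in band column '%s' (row %d)",
                   nms[is_band][j], which(is.na(col))[1]), call. = FALSE)
    }
  }
  X <- as.matrix(band_cols)
  y <- NULL
  if (!is.null(response)) {
    y <- x[[response]]
    if (any(is.na(y))) {
      stop(sprintf("missing value in response column '%s' (row %d)",
                   response, which(is.na(y))[1]), call. = FALSE)
    }
  }
  ids <- if (!is.null(id)) as.character(x[[id]]) else {
    extra <- nms[!is_band & nms != response]
    if (length(extra) == 1 && !is.numeric(x[[extra]])) as.character(x[[extra]])
    else as.character(seq_len(nrow(x)))
  }
  fdata(X, grid, y = y, ids = ids)
}

#' Convert a functional dataset to a band table
#'
#' Inverse of [as_fdata()]: a tibble with an `id` column, the response column
#' (if present), and one column per measurement point named by its grid value.
#'
#' @param data An `fdata` object.
#' @param response Name to give the response column.
#' @return A tibble with `n` rows.
#' @export
as_band_table <- function(data, response = "y") {
  data <- as_fdata(data)
  out <- tibble::as_tibble(as.data.frame(data$X), .name_repair = "minimal")
  names(out) <- as.character(data$grid)
  out <- tibble::add_column(out, id = data$ids, .before = 1)
  if (!is.null(data$y)) {
    out <- tibble::add_column(out, !!response := data$y, .after = 1)
  }
  out
}

#' @export
print.fdata <- function(x, ...) {
  cat(sprintf("<functional dataset> %d curves x %d points on [%g, %g]%s\n",
              nrow(x$X), length(x$grid), min(x$grid), max(x$grid),
              if (is.null(x$y)) "" else ", with response"))
  invisible(x)
}

#' @export
dim.fdata <- function(x) dim(x$X)

# Row subset of an fdata (internal; used by the CV harness)
fdata_subset <- function(data, rows) {
  fdata(data$X[rows, , drop = FALSE], data$grid,
        y = if (is.null(data$y)) NULL else data$y[rows],
        ids = data$ids[rows])
}
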