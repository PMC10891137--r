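#' Regular raster grid geometry
#'
#' A north-up regular grid.  `origin_easting`/`origin_northing` are the
#' coordinates of the OUTER corner of the top-left cell, so the centre of cell
#' (r, c) (1-based) is at
#' `(origin_easting + (c - 0.5) * cell_size, origin_northing - (r - 0.5) * cell_size)`.
#' Row 1 is the northernmost row.
#'
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param cell_size Cell edge length in metres.
#' @param origin_easting,origin_northing Outer corner of the top-left cell (m).
#' @param crs_id Free-text coordinate reference system identifier
#'   (e.g. `"EPSG:2056"`).
#' @return An object of class `lulc_grid`.
#' @export
lulc_grid <- function(n_rows, n_cols, cell_size,
                      origin_easting = 0, origin_northing = n_rows * cell_size,
                      crs_id = "local") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size),
         origin_easting = as.numeric(origin_easting),
         origin_northing = as.numeric(origin_northing),
         crs_id = as.character(crs_id)),
    class = "lulc_grid")
}

#' Test whether two grids are aligned
#'
#' Two grids are aligned iff all geometry fields (and the CRS id) are equal;
#' nothing is ever silently resampled.
#'
#' @param a,b `lulc_grid` objects.
#' @param tol Relative tolerance on the numeric fields.
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "lulc_grid"), inherits(b, "lulc_grid"))
  num_ok <- function(x, y) abs(x - y) <= tol * max(1, abs(x), abs(y))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    num_ok(a$cell_size, b$cell_size) &&
    num_ok(a$origin_easting, b$origin_easting) &&
    num_ok(a$origin_northing, b$origin_northing) &&
    identical(a$crs_id, b$crs_id)
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!grids_aligned(a, b)) {
    stop(sprintf("grid mismatch between %s: (%dx%d, cell %g, origin %g/%g, %s) vs (%dx%d, cell %g, origin %g/%g, %s)",
                 what, a$n_rows, a$n_cols, a$cell_size, a$origin_easting,
                 a$origin_northing, a$crs_id, b$n_rows, b$n_cols, b$cell_size,
                 b$origin_easting, b$origin_northing, b$crs_id), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A `lulc_grid`.
#' @return A list with matrices `easting` and `northing` (n_rows x n_cols).
#' @export
cell_centres <- function(grid) {
  e <- grid$origin_easting + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  n <- grid$origin_northing - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  list(easting = matrix(e, grid$n_rows, grid$n_cols, byrow = TRUE),
       northing = matrix(n, grid$n_rows, grid$n_cols))
}

#' @export
print.lulc_grid <- function(x, ...) {
  cat(sprintf("<lulc_grid> %d x %d cells of %g m, origin (%g, %g), CRS %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_easting,
              x$origin_northing, x$crs_id))
  invisible(x)
}
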