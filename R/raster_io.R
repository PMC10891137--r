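#' Read / write rasters as ESRI ASCII grid
#'
#' Single-band rasters are stored in the plain-text ESRI ASCII grid format
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header
#' followed by north-to-south rows of values).  The CRS identifier travels in
#' a `.prj` sidecar next to the raster.  I/O is lossless for integer codes and
#' grids are never resampled: reading against an `expect_grid` that does not
#' match raises an alignment error.
#'
#' @param path File path (conventionally `.asc`).
#' @param expect_grid Optional `lulc_grid` the file must align with.
#' @return `read_raster()` returns a list with `values` (numeric matrix,
#'   `NA` = nodata) and `grid`.
#' @export
read_raster <- function(path, expect_grid = NULL) {
  lines <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(lines), "[[:space:]]+"), function(p) {
    stats::setNames(as.numeric(p[2]), tolower(p[1]))
  })
  hdr <- unlist(kv)
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  nr <- as.integer(hdr["nrows"]); nc <- as.integer(hdr["ncols"])
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values in %s, found %d", nr * nc, path,
                 length(vals)))
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == hdr["nodata_value"]] <- NA
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) trimws(readLines(prj, n = 1L)) else "local"
  grid <- lulc_grid(nr, nc, hdr["cellsize"],
                    origin_easting = hdr["xllcorner"],
                    origin_northing = hdr["yllcorner"] + nr * hdr["cellsize"],
                    crs_id = crs)
  if (!is.null(expect_grid)) stop_if_misaligned(grid, expect_grid,
                                                sprintf("'%s' and expected grid", path))
  list(values = m, grid = grid)
}

#' @rdname read_raster
#' @param values Numeric or integer matrix (`NA` = nodata).
#' @param grid A `lulc_grid`.
#' @param nodata Value written for `NA` cells.
#' @export
write_raster <- function(values, grid, path, nodata = -9999) {
  stopifnot(all(dim(values) == c(grid$n_rows, grid$n_cols)))
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10g", grid$origin_easting),
           sprintf("yllcorner %.10g",
                   grid$origin_northing - grid$n_rows * grid$cell_size),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs_id, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Read / write a categorical LULC map
#'
#' Codes are validated against the codebook on read; an unknown code is an
#' error naming the offending value.  Nodata cells (code 0 in memory) are
#' stored with the file's nodata value.
#'
#' @param path Raster file path.
#' @param codebook A [class_codebook()].
#' @param expect_grid Optional grid to enforce alignment against.
#' @return An [lulc_map()].
#' @export
read_map <- function(path, codebook, expect_grid = NULL) {
  r <- read_raster(path, expect_grid)
  codes <- r$values
  codes[is.na(codes)] <- 0
  if (any(codes != round(codes))) stop("non-integer class codes in ", path)
  lulc_map(codes, r$grid, codebook)
}

#' @rdname read_map
#' @param map An `lulc_map`.
#' @export
write_map <- function(map, path) {
  v <- map$codes
  v[!map$valid_mask] <- NA
  write_raster(v, map$grid, path, nodata = 0)
}

#' Rasterise a regular point grid
#'
#' Converts a table of regularly spaced points (one per cell) to a categorical
#' map by attributing each point's value to the cell centred on it.  Point
#' spacing must equal `cell_size` (within a relative tolerance of 1e-6) and no
#' two points may fall in one cell; cells with no point are nodata.
#'
#' @param points Data frame with columns `E`, `N` (point coordinates, metres)
#'   and `code` (integer class code).
#' @param cell_size Cell edge length in metres.
#' @param codebook A [class_codebook()].
#' @param crs_id CRS identifier for the derived grid.
#' @return An [lulc_map()] whose grid origin derives from the point extent.
#' @export
points_to_raster <- function(points, cell_size, codebook, crs_id = "local") {
  stopifnot(all(c("E", "N", "code") %in% names(points)), nrow(points) >= 1)
  tol <- 1e-6 * cell_size
  col <- (points$E - min(points$E)) / cell_size
  row <- (max(points$N) - points$N) / cell_size
  if (any(abs(col - round(col)) > tol) || any(abs(row - round(row)) > tol)) {
    stop("point spacing is not a multiple of cell_size (beyond tolerance)")
  }
  col <- as.integer(round(col)) + 1L
  row <- as.integer(round(row)) + 1L
  idx <- cbind(row, col)
  if (anyDuplicated(idx)) stop("duplicate points within one cell")
  grid <- lulc_grid(max(row), max(col), cell_size,
                    origin_easting = min(points$E) - cell_size / 2,
                    origin_northing = max(points$N) + cell_size / 2,
                    crs_id = crs_id)
  codes <- matrix(0L, grid$n_rows, grid$n_cols)
  codes[idx] <- as.integer(points$code)
  lulc_map(codes, grid, codebook)
}

#' Extract cell-centre points from a map
#'
#' Inverse of [points_to_raster()]: returns one row per valid cell with the
#' coordinates of the cell centre.
#'
#' @param map An `lulc_map`.
#' @return Data frame with columns `E`, `N`, `code`.
#' @export
raster_to_points <- function(map) {
  cc <- cell_centres(map$grid)
  keep <- which(map$valid_mask)
  out <- data.frame(E = cc$easting[keep], N = cc$northing[keep],
                    code = map$codes[keep])
  out[order(-out$N, out$E), , drop = FALSE]
}

#' Read / write a GeoStat-dialect point-grid CSV
#'
#' The dialect is a comma-separated table with point coordinates in columns
#' `E` and `N` and one integer class column per time-step.
#'
#' @param path CSV path.
#' @param codebook A [class_codebook()].
#' @param cell_size Cell edge length in metres.
#' @param crs_id CRS identifier.
#' @return A named list of [lulc_map()], one per class column.
#' @export
read_geostat_csv <- function(path, codebook, cell_size, crs_id = "local") {
  tab <- utils::read.csv(path, check.names = FALSE)
  cls_cols <- setdiff(names(tab), c("E", "N"))
  if (!length(cls_cols)) stop("no class columns in ", path)
  maps <- lapply(cls_cols, function(cn) {
    pts <- data.frame(E = tab$E, N = tab$N, code = tab[[cn]])
    pts <- pts[!is.na(pts$code), , drop = FALSE]
    points_to_raster(pts, cell_size, codebook, crs_id)
  })
  stats::setNames(maps, cls_cols)
}

#' @rdname read_geostat_csv
#' @param maps Named list of aligned `lulc_map`s (one class column each).
#' @export
write_geostat_csv <- function(maps, path) {
  stopifnot(length(maps) >= 1)
  for (m in maps[-1]) stop_if_misaligned(maps[[1]]$grid, m$grid)
  base <- raster_to_points(maps[[1]])
  out <- base[, c("E", "N")]
  for (nm in names(maps)) {
    pts <- raster_to_points(maps[[nm]])
    out[[nm]] <- pts$code[match(paste(out$E, out$N), paste(pts$E, pts$N))]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predictor raster stack
#'
#' Named layers on a shared grid, each tagged `continuous` or `categorical`.
#'
#' @param layers Named list of numeric matrices (`NA` = nodata).
#' @param grid A `lulc_grid` all layers must match in dimension.
#' @param types Named character vector, `"continuous"` or `"categorical"` per
#'   layer.
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, grid, types) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            setequal(names(types), names(layers)),
            all(types %in% c("continuous", "categorical")))
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == c(grid$n_rows, grid$n_cols))) {
      stop("layer '", nm, "' does not match the stack grid")
    }
    if (types[[nm]] == "categorical") {
      v <- layers[[nm]][!is.na(layers[[nm]])]
      if (any(v != round(v))) stop("categorical layer '", nm,
                                   "' holds non-integer codes")
    }
  }
  structure(list(layers = layers, grid = grid,
                 types = types[names(layers)]),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d layers on %d x %d grid\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols))
  for (nm in names(x$layers)) cat(sprintf("  %s (%s)\n", nm, x$types[[nm]]))
  invisible(x)
}

#' Write / read a predictor stack as ASCII grids
#'
#' One `.asc` per layer plus a `stack.csv` manifest (layer name, type, file).
#'
#' @param stack A `predictor_stack`.
#' @param dir Directory to hold the files.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(layer = names(stack$layers),
                         type = unname(stack$types[names(stack$layers)]),
                         file = paste0(names(stack$layers), ".asc"),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    write_raster(stack$layers[[manifest$layer[i]]], stack$grid,
                 file.path(dir, manifest$file[i]))
  }
  utils::write.csv(manifest, file.path(dir, "stack.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "stack.csv"),
                              stringsAsFactors = FALSE)
  grid <- NULL
  layers <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- read_raster(file.path(dir, manifest$file[i]), grid)
    if (is.null(grid)) grid <- r$grid
    layers[[manifest$layer[i]]] <- r$values
  }
  predictor_stack(layers, grid,
                  stats::setNames(manifest$type, manifest$layer))
}
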