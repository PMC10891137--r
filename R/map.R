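#' Categorical land-use/land-cover map
#'
#' An integer-coded categorical raster with its grid geometry, class codebook
#' and validity mask.  Cells outside the study area carry the nodata code 0
#' and `valid_mask` FALSE.
#'
#' @param codes Integer matrix (n_rows x n_cols) of class codes; 0 = nodata.
#' @param grid A [lulc_grid()].
#' @param codebook A [class_codebook()]; every valid cell's code must be in it.
#' @param valid_mask Logical matrix; defaults to `codes != 0`.
#' @return An object of class `lulc_map`.
#' @export
lulc_map <- function(codes, grid, codebook, valid_mask = NULL) {
  stopifnot(inherits(grid, "lulc_grid"), inherits(codebook, "class_codebook"))
  codes <- matrix(as.integer(codes), grid$n_rows, grid$n_cols)
  if (is.null(valid_mask)) valid_mask <- codes != 0L
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == dim(codes)))
  codes[!valid_mask] <- 0L
  bad <- setdiff(unique(codes[valid_mask]), codebook$id)
  if (length(bad)) {
    stop("map contains code(s) not in the codebook: ",
         paste(sort(bad), collapse = ", "))
  }
  structure(list(codes = codes, grid = grid, codebook = codebook,
                 valid_mask = valid_mask),
            class = "lulc_map")
}

#' @export
print.lulc_map <- function(x, ...) {
  cat(sprintf("<lulc_map> %d x %d cells (%d valid), %d classes in codebook\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$valid_mask),
              nrow(x$codebook)))
  tab <- table(x$codes[x$valid_mask])
  print(tab)
  invisible(x)
}

#' Dynamic cells of a map
#'
#' Dynamic cells are valid cells whose class is modelled (non-static); they are
#' the universe over which demand and allocation operate.
#'
#' @param map An `lulc_map`.
#' @return Logical matrix.
#' @export
dynamic_mask <- function(map) {
  modelled <- matrix(map$codes %in% modelled_ids(map$codebook),
                     nrow(map$codes), ncol(map$codes))
  map$valid_mask & modelled
}

#' Per-class cell counts over dynamic cells
#'
#' @param map An `lulc_map`.
#' @return Named integer vector over modelled class ids; sums to the number of
#'   dynamic cells.
#' @export
observed_prevalence <- function(map) {
  ids <- modelled_ids(map$codebook)
  dyn <- dynamic_mask(map)
  cnt <- tabulate(map$codes[dyn], nbins = max(map$codebook$id))[ids]
  cnt[is.na(cnt)] <- 0L
  stats::setNames(as.integer(cnt), ids)
}
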