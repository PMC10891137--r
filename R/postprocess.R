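#' Recode every cell of one class to another
#'
#' Used for the glacier step: model-allocated Glacier cells are recoded to
#' Bare land before the mechanistic glacier/lake masks are overlaid.
#'
#' @param map An `lulc_map`.
#' @param source_class,target_class Class ids or names (aliases accepted).
#' @return The recoded `lulc_map`; all other cells untouched.
#' @export
replace_class <- function(map, source_class, target_class) {
  src <- class_id(map$codebook, source_class)
  tgt <- class_id(map$codebook, target_class)
  codes <- map$codes
  codes[codes == src & map$valid_mask] <- tgt
  lulc_map(codes, map$grid, map$codebook, map$valid_mask)
}

#' Overlay externally supplied glacier and lake masks
#'
#' Cells true in `glacier_mask` are set to Glacier, cells true in `lake_mask`
#' to Lakes; where the masks overlap the lake wins (new lakes form in
#' deglaciated terrain).  Mask cells outside the study area are ignored.
#'
#' @param map An `lulc_map` (codebook must contain Glacier and Lakes).
#' @param glacier_mask,lake_mask Logical matrices aligned to the map's grid
#'   (either may be `NULL`).
#' @return The overlaid `lulc_map`.
#' @export
overlay_masks <- function(map, glacier_mask = NULL, lake_mask = NULL) {
  codes <- map$codes
  chk <- function(m, what) {
    if (!all(dim(m) == dim(codes))) stop(what, " mask misaligned with the map grid")
    m & map$valid_mask
  }
  if (!is.null(glacier_mask)) {
    codes[chk(glacier_mask, "glacier")] <- class_id(map$codebook, "Glacier")
  }
  if (!is.null(lake_mask)) {
    codes[chk(lake_mask, "lake")] <- class_id(map$codebook, "Lakes")
  }
  lulc_map(codes, map$grid, map$codebook, map$valid_mask)
}

#' Refine static aggregate classes to fine-resolution codes
#'
#' Replaces each static aggregate code by the fine-resolution code supplied
#' in `subclass_map`, producing a map on the fine codebook.  A fine code
#' outside its aggregate's allowed set (e.g. a transport sub-class under a
#' Lakes cell) is a validation error naming the cell and codes; modelled
#' classes keep their own codes.
#'
#' @param map An `lulc_map` whose codebook declares `fine_ids` for its static
#'   classes (e.g. [swiss_codebook()]).
#' @param subclass_map Integer matrix giving a fine code for every static
#'   cell (other cells ignored).
#' @param fine_codebook Codebook of the refined map; defaults to the Swiss
#'   26-class book built from the aggregate book.
#' @return The refined `lulc_map` on the fine codebook.
#' @export
refine_static_classes <- function(map, subclass_map, fine_codebook = NULL) {
  cb <- map$codebook
  stopifnot(all(dim(subclass_map) == dim(map$codes)))
  if (is.null(fine_codebook)) {
    fine <- swiss_fine_classes()
    keep <- cb[cb$modelled, c("id", "name")]
    fine_codebook <- class_codebook(c(keep$id, fine$fine_id),
                                    c(keep$name, fine$name))
  }
  codes <- map$codes
  for (i in which(cb$static)) {
    agg <- cb$id[i]
    ok_codes <- cb$fine_ids[[i]]
    cells <- which(map$codes == agg & map$valid_mask)
    if (!length(cells)) next
    sub <- subclass_map[cells]
    bad <- which(!(sub %in% ok_codes))
    if (length(bad)) {
      stop(sprintf("fine code %d at cell %d is not a sub-class of aggregate %d ('%s')",
                   sub[bad[1]], cells[bad[1]], agg, cb$name[i]))
    }
    codes[cells] <- sub
  }
  lulc_map(codes, map$grid, fine_codebook, map$valid_mask)
}
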