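#' Construct a class codebook
#'
#' The codebook declares every integer class code a categorical map may carry:
#' which classes are modelled (predicted and allocated) and which are static
#' (held fixed over the whole simulation).  Static aggregate classes may list
#' the fine-resolution sub-class codes they resolve to in the final thematic
#' refinement step.
#'
#' @param id Integer class codes (unique, >= 1; 0 is reserved for nodata).
#' @param name Class names.
#' @param static Logical; static classes are excluded from modelling and
#'   demand.  `modelled = !static`.
#' @param fine_ids Optional list, per class, of the fine-resolution codes the
#'   class resolves to (static aggregates only; modelled classes keep their
#'   own code).
#' @param aliases Optional named character vector mapping alternative names to
#'   canonical ones.
#' @return An object of class `class_codebook` (a data frame with attributes).
#' @export
class_codebook <- function(id, name, static = rep(FALSE, length(id)),
                           fine_ids = NULL, aliases = NULL) {
  id <- as.integer(id)
  stopifnot(!anyDuplicated(id), all(id >= 1), length(name) == length(id),
            length(static) == length(id))
  if (is.null(fine_ids)) fine_ids <- lapply(id, function(i) integer(0))
  cb <- data.frame(id = id, name = as.character(name),
                   modelled = !static, static = static,
                   stringsAsFactors = FALSE)
  cb$fine_ids <- I(fine_ids)
  structure(cb, class = c("class_codebook", "data.frame"),
            aliases = aliases, nodata = 0L)
}

#' The Swiss 17/26-class LULC codebook
#'
#' Encodes the standard Swiss federal-statistics class scheme used by this
#' workflow: 14 modelled classes (codes 1-14), three static aggregates
#' (15 Transportation, 16 Lakes, 17 Rivers), and the fine-resolution codes
#' (15-26) that replace the static aggregates in final maps (Transportation
#' resolves to nine transport sub-classes 15-23, Lakes to 24, Rivers to
#' 25-26).  "Orchard" is an alias of "Horticulture" and "Bare rock" of
#' "Bare land".
#'
#' @return A `class_codebook`.
#' @export
swiss_codebook <- function() {
  nm <- c("Industry", "Building", "Special urban", "Urban green",
          "Horticulture", "Arable", "Grassland", "Alpine grassland",
          "Forest", "Brush", "Trees", "Unproductive vegetation",
          "Bare land", "Glacier", "Transportation", "Lakes", "Rivers")
  static <- c(rep(FALSE, 14), TRUE, TRUE, TRUE)
  fine <- c(lapply(1:14, function(i) integer(0)),
            list(15:23, 24L, 25:26))
  class_codebook(1:17, nm, static, fine,
                 aliases = c("Orchard" = "Horticulture",
                             "Bare rock" = "Bare land"))
}

#' Fine-resolution (26-class) sub-class names of the Swiss scheme
#'
#' @return A data frame with `fine_id`, `name`, and the aggregate `id` each
#'   fine code belongs to.
#' @export
swiss_fine_classes <- function() {
  data.frame(
    fine_id = 15:26,
    name = c("Motorways", "Green motorway environs", "Roads and paths",
             "Green road environments", "Parking areas",
             "Sealed railway areas", "Green railway environments",
             "Airports", "Airfields, green airport environments",
             "Lakes", "Rivers", "Flood protection structures"),
    aggregate_id = c(rep(15L, 9), 16L, 17L, 17L),
    stringsAsFactors = FALSE)
}

#' A minimal codebook for synthetic landscapes
#'
#' @param n_classes Total number of classes (codes `1:n_classes`).
#' @param static_ids Integer codes of static classes (may be empty).
#' @return A `class_codebook`.
#' @export
synthetic_codebook <- function(n_classes, static_ids = integer(0)) {
  stopifnot(n_classes >= 3, all(static_ids %in% seq_len(n_classes)))
  class_codebook(seq_len(n_classes),
                 paste0("Class ", seq_len(n_classes)),
                 static = seq_len(n_classes) %in% static_ids)
}

#' Modelled / static class ids of a codebook
#'
#' @param codebook A `class_codebook`.
#' @return Integer vector of class ids.
#' @export
modelled_ids <- function(codebook) codebook$id[codebook$modelled]

#' @rdname modelled_ids
#' @export
static_ids <- function(codebook) codebook$id[codebook$static]

#' Resolve a class name or id to its id
#'
#' Accepts ids, canonical names, or registered aliases.
#'
#' @param codebook A `class_codebook`.
#' @param x Class id (numeric) or name (character).
#' @return Integer class id.
#' @export
class_id <- function(codebook, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    bad <- setdiff(x, codebook$id)
    if (length(bad)) stop("unknown class id(s): ", paste(bad, collapse = ", "))
    return(x)
  }
  al <- attr(codebook, "aliases")
  xx <- ifelse(x %in% names(al), unname(al[x]), x)
  i <- match(xx, codebook$name)
  if (anyNA(i)) stop("unknown class name(s): ", paste(x[is.na(i)], collapse = ", "))
  codebook$id[i]
}
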