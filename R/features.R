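#' Focal-window class proportion
#'
#' Per-cell fraction of valid in-window cells carrying `class_id`, over a
#' centred square window truncated at the map edges (the denominator is the
#' number of valid in-window cells).  At 100 m cells the customary 5 km
#' neighbourhood corresponds to `window_cells = 51` (50 cells rounded up to
#' the next odd size so the window can be centred).
#'
#' @param map An [lulc_map()].
#' @param class_id Class code; must exist in the map's codebook.
#' @param window_cells Odd window width in cells (>= 1).
#' @return Numeric matrix of fractions (`NA` on nodata cells).
#' @export
neighbourhood_proportion <- function(map, class_id, window_cells) {
  stopifnot(window_cells >= 1, window_cells %% 2 == 1)
  class_id <- class_id(map$codebook, class_id)
  denom <- box_sum(map$valid_mask + 0, window_cells)
  num <- box_sum((map$codes == class_id & map$valid_mask) + 0, window_cells)
  out <- num / pmax(denom, 1)
  out[denom == 0] <- NA
  out[!map$valid_mask] <- NA
  out
}

#' Focal-window dominant class
#'
#' Per-cell modal class over the centred window (valid cells only); ties are
#' broken by the smallest class id; an all-nodata window yields nodata (0).
#'
#' @inheritParams neighbourhood_proportion
#' @return Integer matrix of class codes (0 = nodata window).
#' @export
dominant_class <- function(map, window_cells) {
  stopifnot(window_cells >= 1, window_cells %% 2 == 1)
  ids <- sort(map$codebook$id)
  best_cnt <- matrix(0, map$grid$n_rows, map$grid$n_cols)
  best_id <- matrix(0L, map$grid$n_rows, map$grid$n_cols)
  for (c in ids) {    # ascending id + strict '>' implements the tie rule
    cnt <- box_sum((map$codes == c & map$valid_mask) + 0, window_cells)
    take <- cnt > best_cnt
    best_cnt[take] <- cnt[take]
    best_id[take] <- c
  }
  best_id
}

#' Euclidean distance to the nearest cell of a class
#'
#' Distance in metres from each cell centre to the nearest valid cell centre
#' of `class_id` (0 on the class itself).  If the class is absent everywhere
#' the layer is filled with the `sentinel` distance.
#'
#' @inheritParams neighbourhood_proportion
#' @param sentinel Large distance used when the class is absent (default 1e7 m).
#' @return Numeric matrix of distances in metres.
#' @export
distance_to_class <- function(map, class_id, sentinel = 1e7) {
  class_id <- class_id(map$codebook, class_id)
  nr <- map$grid$n_rows; nc <- map$grid$n_cols
  targets <- which(map$codes == class_id & map$valid_mask)
  if (!length(targets)) {
    return(matrix(sentinel, nr, nc))
  }
  tr <- (targets - 1L) %% nr + 1L
  tc <- (targets - 1L) %/% nr + 1L
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  # chunk over target cells to bound the ncell x ntarget intermediate
  chunk <- max(1L, floor(2e6 / (nr * nc)))
  for (s in seq(1L, length(targets), by = chunk)) {
    i <- s:min(s + chunk - 1L, length(targets))
    for (j in i) {
      d2 <- pmin(d2, (rr - tr[j])^2 + (cc - tc[j])^2)
    }
  }
  sqrt(d2) * map$grid$cell_size
}

#' One-hot encode a categorical vector or layer
#'
#' One binary column/layer per level; on valid entries the encoded set sums
#' to 1.  When `levels` is supplied (the schema frozen at training time), a
#' value outside it is an error — projection must never silently grow the
#' feature space.
#'
#' @param x Integer vector or matrix of category codes (`NA` allowed).
#' @param levels Optional fixed level set; defaults to the observed levels.
#' @param prefix Name prefix for the encoded columns.
#' @return A matrix with one column per level (rows = `length(x)`); for
#'   matrix input, a named list of binary matrices.
#' @export
one_hot <- function(x, levels = NULL, prefix = "x") {
  if (is.matrix(x)) {
    v <- one_hot(as.vector(x), levels, prefix)
    return(lapply(stats::setNames(colnames(v), colnames(v)),
                  function(cn) matrix(v[, cn], nrow(x), ncol(x))))
  }
  obs <- sort(unique(x[!is.na(x)]))
  if (is.null(levels)) levels <- obs
  unseen <- setdiff(obs, levels)
  if (length(unseen)) {
    stop("level(s) ", paste(unseen, collapse = ", "),
         " of '", prefix, "' not present in the frozen encoding schema")
  }
  out <- sapply(levels, function(l) as.numeric(x == l))
  out <- matrix(out, nrow = length(x))
  colnames(out) <- paste0(prefix, "_", levels)
  out
}

#' Greedy correlation filter over continuous features
#'
#' Visits columns in descending order of their association with the response
#' and drops any column whose absolute Pearson correlation with an
#' already-retained column reaches `threshold`.  Zero-variance columns are
#' dropped (with a warning) before ranking.  The selection is computed once on
#' training data and frozen for the whole modelling period.
#'
#' @param x Numeric matrix or data frame of continuous columns.
#' @param ranking Named (or positional) numeric association-with-response
#'   score per column; higher = visited earlier.
#' @param threshold Absolute-correlation cutoff in (0, 1] (default 0.7).
#' @return Character vector of retained column names (in visit order).
#' @export
select_uncorrelated <- function(x, ranking, threshold = 0.7) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 1, threshold > 0, threshold <= 1,
            length(ranking) == ncol(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    drop <- colnames(x)[sds == 0 | is.na(sds)]
    warning("dropping zero-variance column(s): ", paste(drop, collapse = ", "))
    keep <- !(colnames(x) %in% drop)
    x <- x[, keep, drop = FALSE]
    ranking <- ranking[keep]
    if (!ncol(x)) return(character(0))
  }
  ord <- order(-abs(ranking), seq_along(ranking))
  retained <- character(0)
  for (j in ord) {
    nm <- colnames(x)[j]
    if (!length(retained)) {
      retained <- nm
      next
    }
    r <- abs(stats::cor(x[, j], x[, retained, drop = FALSE]))
    if (all(r < threshold, na.rm = TRUE)) retained <- c(retained, nm)
  }
  retained
}

#' Fit / apply column standardisation
#'
#' `fit_scaler()` stores per-column mean and sample standard deviation from a
#' training table; `apply_scaler()` centres and scales any table with those
#' stored parameters.  Zero-sd columns are dropped with a warning.
#'
#' @param x Numeric matrix or data frame.
#' @return `fit_scaler()` returns a `feature_scaler`; `apply_scaler()` the
#'   transformed matrix (only the scaler's columns, in its order).
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sd == 0 | is.na(sd))) {
    drop <- colnames(x)[sd == 0 | is.na(sd)]
    warning("dropping zero-sd column(s): ", paste(drop, collapse = ", "))
    keep <- !(colnames(x) %in% drop)
    mu <- mu[keep]; sd <- sd[keep]
  }
  structure(list(mean = mu, sd = sd), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler` from `fit_scaler()`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(x)
  miss <- setdiff(names(scaler$mean), colnames(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x <- x[, names(scaler$mean), drop = FALSE]
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Build the raw per-cell feature table
#'
#' Assembles, for every dynamic valid cell, the model's raw (pre-encoding)
#' features: the lagged class at the three history steps (categorical), the
#' per-class neighbourhood proportions and the dominant class at t0, and the
#' predictor-stack layers.  Column types travel in the `"types"` attribute;
#' the originating cell indices in `"cells"`.
#'
#' @param history List of exactly 3 aligned `lulc_map`s (t-2, t-1, t0).
#' @param stack A [predictor_stack()] aligned with the maps.
#' @param window_cells Odd focal window width for the neighbourhood features.
#' @return A data frame of raw features over dynamic cells of the t0 map.
#' @export
build_feature_table <- function(history, stack, window_cells = 7) {
  if (length(history) != 3) stop("history must contain exactly 3 maps")
  t0 <- history[[3]]
  for (m in history) stop_if_misaligned(t0$grid, m$grid)
  stop_if_misaligned(t0$grid, stack$grid)
  cells <- which(dynamic_mask(t0))
  feats <- list(lulc_tm2 = history[[1]]$codes[cells],
                lulc_tm1 = history[[2]]$codes[cells],
                lulc_t0 = t0$codes[cells])
  types <- c(lulc_tm2 = "categorical", lulc_tm1 = "categorical",
             lulc_t0 = "categorical")
  for (cid in sort(t0$codebook$id)) {
    nm <- paste0("nprop_", cid)
    feats[[nm]] <- neighbourhood_proportion(t0, cid, window_cells)[cells]
    types[nm] <- "continuous"
  }
  dom <- dominant_class(t0, window_cells)
  feats$dominant_t0 <- dom[cells]
  types["dominant_t0"] <- "categorical"
  for (nm in names(stack$layers)) {
    feats[[nm]] <- stack$layers[[nm]][cells]
    types[nm] <- stack$types[[nm]]
  }
  out <- as.data.frame(feats)
  attr(out, "types") <- types
  attr(out, "cells") <- cells
  attr(out, "window_cells") <- window_cells
  out
}

#' Fit the frozen feature-encoding schema
#'
#' On the training table: ranks continuous columns by absolute point-biserial
#' correlation with the changed-cell indicator, applies the greedy correlation
#' filter, fits the standardiser on the retained continuous columns, and
#' freezes the observed level set of every categorical column.  One-hot
#' (indicator) columns never enter the correlation filter or the
#' standardisation.
#'
#' @param table Raw feature table from [build_feature_table()].
#' @param change_flag Logical vector: did the cell change class at the
#'   response step (association target of the ranking).
#' @param threshold Correlation-filter cutoff (default 0.7).
#' @return A `feature_schema` with the retained columns, scaler and levels.
#' @export
fit_feature_schema <- function(table, change_flag, threshold = 0.7) {
  types <- attr(table, "types")
  cont <- names(types)[types == "continuous"]
  cat <- names(types)[types == "categorical"]
  ranking <- vapply(cont, function(nm) {
    s <- stats::sd(table[[nm]])
    if (is.na(s) || s == 0) 0 else abs(stats::cor(table[[nm]],
                                                  as.numeric(change_flag)))
  }, numeric(1))
  retained <- select_uncorrelated(table[, cont, drop = FALSE], ranking,
                                  threshold)
  scaler <- fit_scaler(table[, retained, drop = FALSE])
  retained <- names(scaler$mean)
  levels <- lapply(stats::setNames(cat, cat),
                   function(nm) sort(unique(table[[nm]])))
  structure(list(continuous = retained, categorical = cat,
                 levels = levels, scaler = scaler, threshold = threshold,
                 raw_columns = names(types), types = types),
            class = "feature_schema")
}

#' Encode a raw feature table under a frozen schema
#'
#' Standardises the retained continuous columns and one-hot encodes the
#' categorical ones with the frozen level sets; a level unseen at fit time is
#' an error.  Returns the numeric model matrix.
#'
#' @param schema A `feature_schema`.
#' @param table Raw feature table with the schema's columns.
#' @return Numeric matrix (rows = table rows).
#' @export
encode_features <- function(schema, table) {
  miss <- setdiff(schema$raw_columns, names(table))
  if (length(miss)) stop("feature table is missing column(s): ",
                         paste(miss, collapse = ", "))
  parts <- list(apply_scaler(schema$scaler,
                             table[, schema$continuous, drop = FALSE]))
  for (nm in schema$categorical) {
    parts[[nm]] <- one_hot(table[[nm]], levels = schema$levels[[nm]],
                           prefix = nm)
  }
  do.call(cbind, parts)
}
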