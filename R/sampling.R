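#' Build the balanced change / no-change training sample
#'
#' Changing cells (response class differs from the t0 class) are rare, so the
#' sample includes every changing valid dynamic cell plus an equal-size simple
#' random sample (without replacement) of non-changing cells.  If there are
#' fewer non-changing than changing cells, all of them are taken with a
#' warning.
#'
#' @param history List of 3 aligned `lulc_map`s (t-2, t-1, t0).
#' @param response Aligned `lulc_map` at the response step (t1).
#' @param stack A [predictor_stack()].
#' @param window_cells Focal window width for neighbourhood features.
#' @param seed Integer seed making the non-changing draw reproducible.
#' @return A `training_table`: data frame of raw features plus columns
#'   `response` (class id at t1), `change_flag` and `synthetic_flag`, with the
#'   feature `types` attribute of [build_feature_table()].
#' @export
balanced_change_sample <- function(history, response, stack,
                                   window_cells = 7, seed = 1) {
  t0 <- history[[3]]
  stop_if_misaligned(t0$grid, response$grid)
  table <- build_feature_table(history, stack, window_cells)
  cells <- attr(table, "cells")
  resp <- response$codes[cells]
  keep <- resp %in% modelled_ids(response$codebook)
  table <- table[keep, , drop = FALSE]
  cells <- cells[keep]
  resp <- resp[keep]
  chg <- resp != t0$codes[cells]
  n_chg <- sum(chg)
  if (n_chg == 0) stop("no change signal: no cell changes class at the response step")
  idx_chg <- which(chg)
  idx_non <- which(!chg)
  take_non <- if (length(idx_non) < n_chg) {
    warning(sprintf("only %d non-changing cells available for %d changing ones; taking all",
                    length(idx_non), n_chg))
    idx_non
  } else {
    with_seed(seed, sort(sample(idx_non, n_chg)))
  }
  rows <- c(idx_chg, take_non)
  out <- table[rows, , drop = FALSE]
  out$response <- resp[rows]
  out$change_flag <- c(rep(TRUE, length(idx_chg)), rep(FALSE, length(take_non)))
  out$synthetic_flag <- FALSE
  rownames(out) <- NULL
  attr(out, "types") <- attr(table, "types")
  attr(out, "cells") <- cells[rows]
  attr(out, "window_cells") <- window_cells
  class(out) <- c("training_table", "data.frame")
  out
}

# Mixed-type SMOTE-NC distance: squared Euclidean over continuous features
# plus med^2 per categorical mismatch, med = median of the continuous
# features' standard deviations.
smote_dist2 <- function(xc, xcat, i, med2) {
  d2 <- if (ncol(xc)) {
    rowSums(sweep(xc, 2, xc[i, ])^2)
  } else numeric(nrow(xcat))
  if (ncol(xcat)) {
    mism <- rowSums(sweep(as.matrix(xcat), 2, as.matrix(xcat)[i, ], "!=") + 0)
    d2 <- d2 + mism * med2
  }
  d2
}

#' SMOTE-NC oversampling of minority classes
#'
#' Oversamples the CHANGING subset of a training table so that every response
#' class reaches its target row count (by default the count of the most
#' prevalent class within the changing subset).  For each synthetic row a seed
#' row of the class is drawn, one of its `k` nearest same-class neighbours is
#' picked under the mixed metric (Euclidean on continuous features, each
#' categorical mismatch adding `med^2`, where `med` is the median of the
#' continuous features' standard deviations); continuous values are
#' interpolated as `seed + u * (neighbour - seed)` with `u ~ Uniform(0, 1)`
#' and categorical values take the mode among the `k` neighbours (ties to the
#' smallest level).  Classes with a single changing row are duplicated with a
#' warning.  Non-synthetic rows are never altered; non-changing rows are
#' passed through untouched.
#'
#' @param table A `training_table` (from [balanced_change_sample()]).
#' @param k Number of nearest neighbours (default 5).
#' @param targets Optional named per-class target counts (>= current counts);
#'   default: every changing class is raised to the most prevalent changing
#'   class's count.
#' @param seed Integer seed.
#' @return The augmented `training_table`; synthetic rows carry
#'   `synthetic_flag = TRUE` and the augmentation provenance (seed row,
#'   neighbour row, interpolation weight per synthetic row) is attached as
#'   attribute `"provenance"`.
#' @export
smote_nc <- function(table, k = 5, targets = NULL, seed = 1) {
  stopifnot(k >= 1)
  types <- attr(table, "types")
  cont <- names(types)[types == "continuous"]
  cats <- names(types)[types == "categorical"]
  chg <- which(table$change_flag & !table$synthetic_flag)
  counts <- table(factor(table$response[chg]))
  if (is.null(targets)) {
    targets <- stats::setNames(rep(max(counts), length(counts)),
                               names(counts))
  }
  if (any(targets[names(counts)] < counts)) {
    stop("targets must be >= current per-class counts")
  }
  xc_all <- as.matrix(table[chg, cont, drop = FALSE])
  med <- stats::median(apply(xc_all, 2, stats::sd))
  if (is.na(med)) med <- 1
  med2 <- med^2

  new_rows <- list()
  prov <- list()
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- as.integer(targets[[cl]] - counts[[cl]])
      if (need <= 0) next
      rows_cl <- chg[table$response[chg] == as.numeric(cl)]
      if (length(rows_cl) == 1) {
        warning("class ", cl, " has a single changing row; duplicating it")
        dup <- table[rep(rows_cl, need), , drop = FALSE]
        dup$synthetic_flag <- TRUE
        new_rows[[cl]] <- dup
        prov[[cl]] <- data.frame(class = as.numeric(cl),
                                 seed_row = rows_cl, neighbour_row = rows_cl,
                                 u = 0)
        next
      }
      xc <- as.matrix(table[rows_cl, cont, drop = FALSE])
      xcat <- table[rows_cl, cats, drop = FALSE]
      kk <- min(k, length(rows_cl) - 1L)
      nn <- lapply(seq_along(rows_cl), function(i) {
        d2 <- smote_dist2(xc, xcat, i, med2)
        d2[i] <- Inf
        order(d2, seq_along(d2))[seq_len(kk)]   # ties broken by row order
      })
      seed_pick <- sample(seq_along(rows_cl), need, replace = TRUE)
      nb_pick <- vapply(seed_pick, function(i) nn[[i]][sample.int(kk, 1)],
                        integer(1))
      u <- stats::runif(need)
      synth <- table[rows_cl[seed_pick], , drop = FALSE]
      if (length(cont)) {
        synth[, cont] <- xc[seed_pick, , drop = FALSE] +
          u * (xc[nb_pick, , drop = FALSE] - xc[seed_pick, , drop = FALSE])
      }
      for (cn in cats) {
        modes <- vapply(seq_len(need), function(j) {
          vals <- xcat[[cn]][nn[[seed_pick[j]]]]
          tab <- table(vals)
          as.numeric(names(tab)[which.max(tab)])  # ties -> smallest level
        }, numeric(1))
        storage.mode(modes) <- storage.mode(table[[cn]])
        synth[[cn]] <- modes
      }
      synth$synthetic_flag <- TRUE
      new_rows[[cl]] <- synth
      prov[[cl]] <- data.frame(class = as.numeric(cl),
                               seed_row = rows_cl[seed_pick],
                               neighbour_row = rows_cl[nb_pick], u = u)
    }
  })
  out <- rbind(table, do.call(rbind, new_rows))
  rownames(out) <- NULL
  attr(out, "types") <- types
  attr(out, "window_cells") <- attr(table, "window_cells")
  attr(out, "provenance") <- if (length(prov)) do.call(rbind, prov) else NULL
  class(out) <- c("training_table", "data.frame")
  out
}
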