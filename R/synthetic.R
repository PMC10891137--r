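#' Configuration of the synthetic landscape generator
#'
#' The generator produces a multi-temporal categorical raster series with
#' known, recoverable dynamics: at each step a small fraction of dynamic cells
#' (`change_rate`) is redrawn from a multinomial logit whose linear predictor
#' combines a class intercept (optionally drifting over time), continuous
#' predictor effects, and the same-class focal proportion in a centred window.
#' Static-class cells never change.  This emulates the statistical structure
#' of observed national LULC series — rare changing cells, strongly imbalanced
#' class prevalences, spatial autocorrelation, and a static-class mask —
#' without any real geography.
#'
#' @param grid_rows,grid_cols Grid dimensions (default 100 x 100).
#' @param cell_size Cell edge length in metres (default 100).
#' @param n_classes Number of classes including static ones (>= 3, default 6).
#' @param n_steps Number of observed time-steps (>= 4, default 4).
#' @param change_rate Fraction of dynamic cells redrawn per step, in (0, 1)
#'   (default 0.05; redrawn cells always change class).
#' @param class_drift Per-class prevalence trend per step; must sum to ~0 so
#'   prevalences remain a partition.  Applied as a drift on class intercepts.
#' @param predictor_effects Matrix (n_classes x 3) of coefficients on the
#'   continuous predictors (elevation-like gradient and two autocorrelated
#'   Gaussian fields).  Default gives each dynamic class one signature axis.
#' @param neighbourhood_effect Coefficient on the same-class focal proportion
#'   (default 3, giving visibly clumped dynamics).
#' @param static_class_ids Classes held fixed (default: the last class, laid
#'   out as contiguous low-lying "water" blobs).
#' @param window_cells Odd focal window width in cells used by the generator's
#'   neighbourhood term (default 7).
#' @param seed Integer seed; one seed drives all randomness.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(grid_rows = 100, grid_cols = 100, cell_size = 100,
                             n_classes = 6, n_steps = 4, change_rate = 0.05,
                             class_drift = NULL, predictor_effects = NULL,
                             neighbourhood_effect = 3,
                             static_class_ids = n_classes,
                             window_cells = 7, seed = 7) {
  if (n_classes < 3) stop("n_classes must be >= 3")
  if (grid_rows < 1 || grid_cols < 1) stop("zero-area grid")
  if (n_steps < 4) stop("n_steps must be >= 4")
  if (!(change_rate >= 0 && change_rate < 1)) stop("change_rate must be in [0, 1)")
  static_class_ids <- as.integer(static_class_ids)
  dyn_ids <- setdiff(seq_len(n_classes), static_class_ids)
  if (length(dyn_ids) < 2) stop("need at least two dynamic classes")
  if (change_rate > 0 && change_rate * grid_rows * grid_cols < 1) {
    stop("change_rate too small: fewer than one changing cell per step")
  }
  if (is.null(class_drift)) {
    class_drift <- numeric(n_classes)
    class_drift[dyn_ids[1]] <- 0.01
    class_drift[dyn_ids[2]] <- -0.01
  }
  if (abs(sum(class_drift)) > 1e-8) stop("class_drift must sum to 0")
  if (is.null(predictor_effects)) {
    predictor_effects <- matrix(0, n_classes, 3)
    sgn <- c(1.5, -1.5)
    for (k in seq_along(dyn_ids)) {
      predictor_effects[dyn_ids[k], ((k - 1) %/% 2) %% 3 + 1] <-
        sgn[(k - 1) %% 2 + 1]
    }
  }
  stopifnot(nrow(predictor_effects) == n_classes, ncol(predictor_effects) == 3)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size = cell_size, n_classes = as.integer(n_classes),
                 n_steps = as.integer(n_steps), change_rate = change_rate,
                 class_drift = class_drift,
                 predictor_effects = predictor_effects,
                 neighbourhood_effect = neighbourhood_effect,
                 static_class_ids = static_class_ids,
                 window_cells = as.integer(window_cells),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Per-class focal same-class proportions for the generator's neighbourhood
# term; returns an ncell x n_classes matrix of window fractions.
focal_class_props <- function(codes, n_classes, w) {
  valid <- codes != 0L
  denom <- box_sum(valid + 0, w)
  out <- matrix(0, length(codes), n_classes)
  for (c in seq_len(n_classes)) {
    num <- box_sum((codes == c) + 0, w)
    out[, c] <- as.vector(num / pmax(denom, 1))
  }
  out
}

#' Generate a synthetic multi-temporal landscape
#'
#' @param config A [landscape_config()].
#' @return A list with `maps` (list of `n_steps` aligned [lulc_map()]s),
#'   `stack` (a [predictor_stack()] with layers `elev`, `field1`, `field2`
#'   continuous and `region` categorical), `codebook`, and `truth` — the
#'   generative record (coefficients, per-step prevalence counts over dynamic
#'   classes, and the changed-cell indices per step).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    nr <- config$grid_rows; nc <- config$grid_cols
    K <- config$n_classes
    grid <- lulc_grid(nr, nc, config$cell_size,
                      origin_easting = 2600000,
                      origin_northing = 1200000 + nr * config$cell_size,
                      crs_id = "EPSG:2056")
    cb <- synthetic_codebook(K, config$static_class_ids)

    # predictors: elevation-like gradient + two autocorrelated fields +
    # contiguous categorical regions (nearest of 4 random seed points)
    rowgrad <- matrix(seq(-1, 1, length.out = nr), nr, nc)
    elev <- rowgrad + 0.6 * box_blur(matrix(stats::rnorm(nr * nc), nr, nc), 9L)
    elev <- (elev - mean(elev)) / stats::sd(elev)
    gfield <- function() {
      f <- box_blur(matrix(stats::rnorm(nr * nc), nr, nc), 9L)
      (f - mean(f)) / stats::sd(f)
    }
    field1 <- gfield(); field2 <- gfield()
    n_reg <- 4L
    sr <- stats::runif(n_reg, 1, nr); sc <- stats::runif(n_reg, 1, nc)
    rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc,
                                                    byrow = TRUE)
    d2 <- sapply(seq_len(n_reg), function(i) (rr - sr[i])^2 + (cc - sc[i])^2)
    region <- matrix(max.col(-d2, ties.method = "first"), nr, nc)
    stack <- predictor_stack(
      list(elev = elev, field1 = field1, field2 = field2, region = region),
      grid, c(elev = "continuous", field1 = "continuous",
              field2 = "continuous", region = "categorical"))

    X <- cbind(as.vector(elev), as.vector(field1), as.vector(field2))
    B <- config$predictor_effects
    eta0 <- X %*% t(B)                       # ncell x K, class effects

    dyn_ids <- setdiff(seq_len(K), config$static_class_ids)
    # static blobs: lowest elevation decile, only when static classes exist
    static_cells <- integer(0)
    codes <- matrix(0L, nr, nc)
    if (length(config$static_class_ids)) {
      thr <- stats::quantile(elev, 0.08)
      static_cells <- which(as.vector(elev) <= thr)
      per <- split(static_cells,
                   rep_len(seq_along(config$static_class_ids),
                           length(static_cells)))
      for (i in seq_along(config$static_class_ids)) {
        codes[per[[i]]] <- config$static_class_ids[i]
      }
    }
    dyn_cells <- setdiff(seq_len(nr * nc), static_cells)

    # initial map: draw from the logit without neighbourhood, then two
    # neighbourhood-aware sweeps to build spatial coherence
    draw_class <- function(eta, cells, exclude_current = NULL) {
      e <- eta[cells, dyn_ids, drop = FALSE]
      if (!is.null(exclude_current)) {
        cur <- match(exclude_current, dyn_ids)
        e[cbind(seq_along(cells), cur)] <- -Inf
      }
      e <- e - apply(e, 1, max)
      p <- exp(e); p <- p / rowSums(p)
      u <- stats::runif(length(cells))
      cum <- t(apply(p, 1, cumsum))
      dyn_ids[max.col(cum >= u, ties.method = "first")]
    }
    codes[dyn_cells] <- draw_class(eta0, dyn_cells)
    for (sweep in 1:2) {
      fp <- focal_class_props(codes, K, config$window_cells)
      eta <- eta0 + config$neighbourhood_effect * fp
      codes[dyn_cells] <- draw_class(eta, dyn_cells)
    }

    maps <- vector("list", config$n_steps)
    maps[[1]] <- lulc_map(codes, grid, cb,
                          valid_mask = matrix(TRUE, nr, nc))
    changed <- vector("list", config$n_steps)
    changed[[1]] <- integer(0)
    prev_counts <- matrix(0L, config$n_steps, length(dyn_ids),
                          dimnames = list(NULL, dyn_ids))
    count_dyn <- function(codes) {
      tabulate(codes[dyn_cells], nbins = K)[dyn_ids]
    }
    prev_counts[1, ] <- count_dyn(codes)

    for (t in 2:config$n_steps) {
      sel <- dyn_cells[stats::runif(length(dyn_cells)) < config$change_rate]
      new_codes <- codes
      if (length(sel)) {
        fp <- focal_class_props(codes, K, config$window_cells)
        # drift enters as a per-step shift of the class intercepts; the gain
        # of 25 makes a drift of 0.01/step move the redraw equilibrium by a
        # few tenths of a percent of the landscape per step
        drift <- matrix(config$class_drift * (t - 1) * 25, length(sel), K,
                        byrow = TRUE)
        eta <- eta0[sel, , drop = FALSE] +
          config$neighbourhood_effect * fp[sel, , drop = FALSE] + drift
        full_eta <- matrix(-Inf, nr * nc, K)
        full_eta[sel, ] <- eta
        new_codes[sel] <- draw_class(full_eta, sel,
                                     exclude_current = codes[sel])
      }
      changed[[t]] <- which(new_codes != codes)
      codes <- new_codes
      maps[[t]] <- lulc_map(codes, grid, cb,
                            valid_mask = matrix(TRUE, nr, nc))
      prev_counts[t, ] <- count_dyn(codes)
    }

    truth <- list(predictor_effects = B,
                  neighbourhood_effect = config$neighbourhood_effect,
                  class_drift = config$class_drift,
                  dynamic_ids = dyn_ids,
                  n_dynamic = length(dyn_cells),
                  prevalence = prev_counts,
                  changed = changed)
    list(maps = maps, stack = stack, codebook = cb, truth = truth)
  })
}

#' Write a complete runnable fixture to disk
#'
#' Writes one ASCII-grid raster per time-step, the predictor stack, a
#' GeoStat-dialect point-grid CSV of the series, a demand CSV (fractions of
#' the dynamic area, extrapolated linearly from the observed maps) and one
#' all-permissive transition CSV per future period, so the whole pipeline can
#' run from files alone.
#'
#' @param config A [landscape_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_future Number of future steps covered by the demand file.
#' @return Invisibly, the generated landscape (as [generate_landscape()]).
#' @export
write_fixture <- function(config, out_dir, n_future = 3) {
  land <- generate_landscape(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(land$maps)) {
    write_map(land$maps[[t]], file.path(out_dir, sprintf("lulc_t%d.asc", t)))
  }
  write_stack(land$stack, file.path(out_dir, "predictors"))
  write_geostat_csv(stats::setNames(land$maps,
                                    sprintf("LU%d", seq_along(land$maps))),
                    file.path(out_dir, "points.csv"))
  utils::write.csv(land$codebook[, c("id", "name", "modelled", "static")],
                   file.path(out_dir, "codebook.csv"), row.names = FALSE)

  obs <- t(sapply(land$maps, observed_prevalence))
  sched <- extrapolate_demand(obs, n_future = n_future)
  write_demand_csv(sched, file.path(out_dir, "demand.csv"))

  ids <- modelled_ids(land$codebook)
  perm <- transition_matrix(matrix(1L, length(ids), length(ids),
                                   dimnames = list(ids, ids)), "all")
  for (p in seq_len(n_future)) {
    write_transition_csv(perm, file.path(out_dir,
                                         sprintf("transitions_p%d.csv", p)))
  }
  invisible(land)
}
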