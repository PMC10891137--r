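#' Demand-constrained CLUE-S allocation of one time-step
#'
#' Combines per-cell, per-class suitability with per-class demand and binary
#' transition rules into a single categorical map.  The iterative scheme
#' maintains an additive iteration parameter `lambda_c` per class (all zero
#' initially); each pass assigns every competing dynamic cell to the
#' `argmax` over its ALLOWED destination classes of
#' `suitability + lambda_c` (a forbidden destination scores `-Inf`, so no
#' `lambda` can resurrect it), compares the per-class allocated counts to the
#' demand, and updates
#' `lambda_c <- lambda_c + step * (demanded - allocated) / dynamic_total`,
#' with the per-class step damped multiplicatively whenever the deviation
#' changes sign (oscillation).  Iteration stops when the largest absolute
#' deviation is within `tolerance` or `max_iter` is reached; ties are broken
#' deterministically (lowest class id, then row-major cell order).  Cells
#' whose current class forbids every move are pre-assigned and removed from
#' competition before demand feasibility is checked.  If the lambda iteration
#' ends above tolerance, a deterministic greedy repair pass moves the cells
#' with the smallest suitability loss (legal moves only) from over- to
#' under-allocated classes until demand is met within tolerance.
#'
#' @param suitability A `suitability_stack` (per-class probability layers
#'   summing to 1 on dynamic cells).
#' @param current The current `lulc_map`.
#' @param demand Named per-class target cell counts (names = modelled class
#'   ids); must sum to the number of dynamic cells.
#' @param rules A [transition_matrix()] over the modelled classes.
#' @param tolerance Allowed per-class deviation in cells (default
#'   `max(1, 0.0005 * dynamic_total)`).
#' @param max_iter Maximum lambda iterations (default 1000).
#' @param step Initial lambda step (default 0.5).
#' @param damping Multiplicative step damping on oscillation (default 0.9).
#' @return An `allocation_result`: the allocated `lulc_map`, iterations used,
#'   per-class final deviation (allocated - demanded, cells), a convergence
#'   flag and the final lambda vector.
#' @export
clues_allocate <- function(suitability, current, demand, rules,
                           tolerance = NULL, max_iter = 1000,
                           step = 0.5, damping = 0.9) {
  stopifnot(inherits(suitability, "suitability_stack"),
            inherits(current, "lulc_map"),
            inherits(rules, "transition_matrix"))
  stop_if_misaligned(suitability$grid, current$grid)
  classes <- suitability$classes
  K <- length(classes)
  lab <- as.character(classes)
  if (!setequal(rownames(rules$mat), lab)) {
    stop("transition matrix labels do not match the suitability classes")
  }
  rmat <- rules$mat[lab, lab, drop = FALSE]

  dyn <- which(dynamic_mask(current))
  n_dyn <- length(dyn)
  if (is.null(tolerance)) tolerance <- max(1, 5e-4 * n_dyn)
  demand <- demand[lab]
  if (anyNA(demand)) stop("demand must name every modelled class")
  if (abs(sum(demand) - n_dyn) > 1e-6) {
    stop(sprintf("demand sums to %g but there are %d dynamic cells",
                 sum(demand), n_dyn))
  }

  S <- sapply(suitability$layers[lab], function(m) m[dyn])
  S <- matrix(S, n_dyn, K, dimnames = list(NULL, lab))
  if (anyNA(S)) stop("suitability is missing on some dynamic cells")
  if (any(S < -1e-9 | S > 1 + 1e-9) ||
      any(abs(rowSums(S) - 1) > 1e-6)) {
    stop("suitability layers are not a per-cell probability simplex")
  }

  cur <- current$codes[dyn]
  cur_k <- match(cur, classes)
  allow <- rmat[cur_k, , drop = FALSE]          # n_dyn x K logical

  # cells whose current class only persists are out of the competition
  locked <- rowSums(allow) == 1L
  assigned <- integer(n_dyn)
  assigned[locked] <- cur_k[locked]
  comp <- which(!locked)
  base_counts <- tabulate(assigned[locked], nbins = K)

  # feasibility: enough convertible cells for every class's demand
  cap <- base_counts + colSums(allow[comp, , drop = FALSE])
  short <- demand > cap + 1e-9
  if (any(short)) {
    stop("demand infeasible under the transition rules for class(es): ",
         paste(lab[short], collapse = ", "),
         " (demanded ", paste(round(demand[short]), collapse = ", "),
         ", convertible ", paste(cap[short], collapse = ", "), ")")
  }

  Sc <- S[comp, , drop = FALSE]
  Sc[!allow[comp, , drop = FALSE]] <- -Inf
  lambda <- rep(0, K)
  step_c <- rep(step, K)
  prev_dev <- rep(NA_real_, K)
  best <- list(maxdev = Inf, assigned = NULL, lambda = lambda, iter = 0L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    score <- sweep(Sc, 2, lambda, "+")
    pick <- max.col(score, ties.method = "first")  # lowest class id on ties
    counts <- base_counts + tabulate(pick, nbins = K)
    dev <- counts - demand
    if (max(abs(dev)) < best$maxdev) {
      best <- list(maxdev = max(abs(dev)), assigned = pick, lambda = lambda,
                   iter = iter)
    }
    if (max(abs(dev)) <= tolerance || iter >= max_iter) break
    osc <- !is.na(prev_dev) & sign(dev) != sign(prev_dev) & dev != 0 &
      prev_dev != 0
    step_c[osc] <- step_c[osc] * damping
    prev_dev <- dev
    lambda <- lambda + step_c * (demand - counts) / n_dyn
  }
  converged <- best$maxdev <= tolerance
  pick <- best$assigned
  lambda <- best$lambda

  if (!converged) {
    rep_out <- repair_allocation(Sc, pick, base_counts, demand, tolerance)
    pick <- rep_out$pick
    converged <- rep_out$converged
  }
  counts <- base_counts + tabulate(pick, nbins = K)
  assigned[comp] <- pick

  codes <- current$codes
  codes[dyn] <- classes[assigned]
  map <- lulc_map(codes, current$grid, current$codebook,
                  valid_mask = current$valid_mask)
  structure(list(map = map, iterations = best$iter,
                 deviation = stats::setNames(counts - demand, lab),
                 converged = converged,
                 lambda = stats::setNames(lambda, lab)),
            class = "allocation_result")
}

# Deterministic greedy repair: while some class is over target and another
# under, move the competing cell whose suitability loss is smallest (ties:
# row-major cell order) from an over- to an under-allocated class, along a
# legal transition.
repair_allocation <- function(Sc, pick, base_counts, demand, tolerance) {
  K <- ncol(Sc)
  repeat {
    counts <- base_counts + tabulate(pick, nbins = K)
    dev <- counts - demand
    if (max(abs(dev)) <= tolerance) return(list(pick = pick, converged = TRUE))
    over <- which(dev > 0)
    under <- which(dev < 0)
    if (!length(over) || !length(under)) {
      return(list(pick = pick, converged = max(abs(dev)) <= tolerance))
    }
    best_loss <- Inf; best_cell <- 0L; best_to <- 0L
    for (o in over) {
      cells <- which(pick == o)
      if (!length(cells)) next
      gain <- Sc[cells, under, drop = FALSE]  # -Inf where illegal
      loss <- Sc[cbind(cells, rep(o, length(cells)))] - gain
      j <- which(loss == min(loss), arr.ind = TRUE)
      if (!nrow(j)) next
      j <- j[order(j[, 1], j[, 2]), , drop = FALSE][1, ]
      l <- loss[j[1], j[2]]
      if (is.finite(l) && l < best_loss) {
        best_loss <- l
        best_cell <- cells[j[1]]
        best_to <- under[j[2]]
      }
    }
    if (!is.finite(best_loss)) {
      return(list(pick = pick, converged = FALSE))  # no legal move remains
    }
    pick[best_cell] <- best_to
  }
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> %s after %d iterations; max |dev| = %g cells\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, max(abs(x$deviation))))
  invisible(x)
}

#' Run the full multi-step forecast
#'
#' For each future step: project the suitability stack from the current 3-map
#' history ([project_step()]), allocate under that step's demand and rules
#' ([clues_allocate()]), apply any post-processing (glacier replacement and
#' mask overlays), and shift the history window.
#'
#' @param model A `suitability_model`.
#' @param history List of 3 aligned maps ending at the last observed step.
#' @param stack Static predictor stack.
#' @param demand A [demand_schedule()]; its future (non-observed) steps drive
#'   the forecast.
#' @param rules Single [transition_matrix()] or list of one per future step.
#' @param n_steps Number of steps to forecast (default: all future demand
#'   steps).
#' @param timestep_predictors Optional list (per step) of named time-varying
#'   layers passed to [project_step()].
#' @param postprocess Optional function `(lulc_map, step) -> lulc_map`
#'   applied after each allocation.
#' @param window_cells Focal window width.
#' @param ... Passed to [clues_allocate()] (tolerance, max_iter, ...).
#' @return List with `results` (one `allocation_result` per step) and `maps`
#'   (the post-processed map sequence).
#' @export
run_forecast <- function(model, history, stack, demand, rules,
                         n_steps = NULL, timestep_predictors = NULL,
                         postprocess = NULL, window_cells = 7, ...) {
  stopifnot(length(history) == 3, inherits(demand, "demand_schedule"))
  fut <- which(!demand$observed)
  if (is.null(n_steps)) n_steps <- length(fut)
  if (n_steps > length(fut)) stop("demand schedule covers only ",
                                  length(fut), " future steps")
  if (inherits(rules, "transition_matrix")) {
    rules <- rep(list(rules), n_steps)
  }
  if (length(rules) < n_steps) stop("need one transition matrix per step (missing for step ",
                                    length(rules) + 1, ")")
  results <- list()
  maps <- list()
  for (s in seq_len(n_steps)) {
    tp <- if (!is.null(timestep_predictors)) timestep_predictors[[s]] else NULL
    suit <- project_step(model, history, stack, tp, window_cells)
    dem <- demand$counts[fut[s], ]
    res <- clues_allocate(suit, history[[3]], dem, rules[[s]], ...)
    out_map <- res$map
    if (!is.null(postprocess)) out_map <- postprocess(out_map, s)
    results[[s]] <- res
    maps[[s]] <- out_map
    history <- list(history[[2]], history[[3]], out_map)
  }
  list(results = results, maps = maps)
}
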