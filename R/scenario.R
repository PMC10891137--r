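#' Demand schedule
#'
#' Per-time-step target cell counts per modelled class.  Internally demand is
#' held in cells; the CSV interface uses fractions of the dynamic area.  At
#' every step the targets sum exactly to `dynamic_total`.
#'
#' @param counts Numeric matrix (steps x classes) of cell counts; column
#'   names are modelled class ids.
#' @param dynamic_total Number of dynamic (valid, non-static) cells.
#' @param step_labels Optional row labels.
#' @param observed Logical vector marking observed (vs future) steps.
#' @return A `demand_schedule`.
#' @export
demand_schedule <- function(counts, dynamic_total,
                            step_labels = NULL, observed = NULL) {
  counts <- as.matrix(counts)
  if (is.null(step_labels)) step_labels <- paste0("t", seq_len(nrow(counts)))
  if (is.null(observed)) observed <- rep(FALSE, nrow(counts))
  stopifnot(all(counts >= 0), length(observed) == nrow(counts))
  sums <- rowSums(counts)
  if (any(abs(sums - dynamic_total) > 1e-6)) {
    stop("demand must sum to dynamic_total at every step (found ",
         paste(round(sums[abs(sums - dynamic_total) > 1e-6]), collapse = ", "),
         " vs ", dynamic_total, ")")
  }
  rownames(counts) <- step_labels
  structure(list(counts = counts, dynamic_total = dynamic_total,
                 observed = observed),
            class = "demand_schedule")
}

#' @export
print.demand_schedule <- function(x, ...) {
  cat(sprintf("<demand_schedule> %d steps x %d classes, dynamic total %d\n",
              nrow(x$counts), ncol(x$counts), x$dynamic_total))
  print(round(x$counts, 1))
  invisible(x)
}

# proportional rebalancing of one step's counts so they sum to total;
# `free` marks classes allowed to absorb the residual.  Negative values are
# clamped to zero first; clamped classes leave the free set.
rebalance_step <- function(counts, total, free = rep(TRUE, length(counts))) {
  counts <- pmax(counts, 0)
  for (i in 1:(length(counts) + 1)) {
    resid <- total - sum(counts)
    if (abs(resid) < 1e-9) break
    if (!any(free)) stop("demand infeasible: all classes constrained but counts do not sum to the dynamic total")
    pool <- sum(counts[free])
    if (pool <= 0) {
      counts[free] <- resid / sum(free)
    } else {
      counts[free] <- counts[free] * (pool + resid) / pool
    }
    neg <- counts < 0
    counts[neg] <- 0
    free <- free & !neg
  }
  counts
}

#' Linear extrapolation of demand
#'
#' Continues, for each class, the straight line through the LAST TWO observed
#' prevalence counts.  Negative projections are clamped to zero and each
#' step's counts are rescaled proportionally over the unclamped classes so
#' they sum to the dynamic total; finally counts are rounded to whole cells
#' preserving the total (largest-remainder).
#'
#' @param observed Matrix (>= 2 observed steps x classes) of cell counts;
#'   column names are class ids (as from [observed_prevalence()] rows).
#' @param n_future Number of future steps to project.
#' @param step_labels Optional labels for all steps.
#' @return A [demand_schedule()] holding the observed and future steps.
#' @export
extrapolate_demand <- function(observed, n_future, step_labels = NULL) {
  observed <- as.matrix(observed)
  stopifnot(nrow(observed) >= 2, n_future >= 1)
  total <- sum(observed[nrow(observed), ])
  last <- observed[nrow(observed), ]
  slope <- last - observed[nrow(observed) - 1, ]
  fut <- matrix(NA_real_, n_future, ncol(observed),
                dimnames = list(NULL, colnames(observed)))
  for (j in seq_len(n_future)) {
    raw <- last + j * slope
    clamped <- raw < 0
    bal <- rebalance_step(raw, total, free = !clamped)
    fut[j, ] <- round_preserve_sum(bal, total)
  }
  demand_schedule(rbind(observed, fut), total, step_labels,
                  observed = c(rep(TRUE, nrow(observed)),
                               rep(FALSE, n_future)))
}

#' Policy override on the demand schedule
#'
#' @param classes Modelled class ids (or names resolvable via the codebook
#'   at application time) the override applies to.
#' @param action `"freeze"` — from `start_step` on, the class keeps the value
#'   it had at the last step before the freeze; `"replacement-only"` — the
#'   class may never exceed that value (losses are allowed, gains only up to
#'   replacement).
#' @param start_step First (1-based, over all schedule steps) step the
#'   override applies to.
#' @return A `policy_override`.
#' @export
policy_override <- function(classes, action = c("freeze", "replacement-only"),
                            start_step) {
  action <- match.arg(action)
  structure(list(classes = classes, action = action,
                 start_step = as.integer(start_step)),
            class = "policy_override")
}

#' Apply policy overrides to a demand schedule
#'
#' Overridden classes are pinned (frozen) or capped (replacement-only) from
#' their start step on; the resulting surplus or deficit at each step is
#' redistributed proportionally over the unconstrained classes so every step
#' still sums to the dynamic total.  Applying the same overrides twice is a
#' no-op.
#'
#' @param schedule A [demand_schedule()].
#' @param overrides List of [policy_override()]s (or a single one).
#' @param codebook Optional codebook used to resolve class names.
#' @return The adjusted `demand_schedule`.
#' @export
apply_policy_overrides <- function(schedule, overrides, codebook = NULL) {
  if (inherits(overrides, "policy_override")) overrides <- list(overrides)
  if (!length(overrides)) return(schedule)
  counts <- schedule$counts
  ids <- colnames(counts)
  for (ov in overrides) {
    cls <- if (!is.null(codebook)) class_id(codebook, ov$classes) else ov$classes
    cls <- as.character(cls)
    bad <- setdiff(cls, ids)
    if (length(bad)) stop("override names unknown class(es): ",
                          paste(bad, collapse = ", "))
    s0 <- max(ov$start_step, 2L)
    anchor <- counts[s0 - 1L, cls]
    for (s in seq(from = min(ov$start_step, nrow(counts)),
                  to = nrow(counts))) {
      if (s < ov$start_step) next
      constrained <- rep(FALSE, ncol(counts))
      names(constrained) <- ids
      if (ov$action == "freeze") {
        counts[s, cls] <- anchor
      } else {
        counts[s, cls] <- pmin(counts[s, cls], anchor)
      }
      constrained[cls] <- TRUE
      counts[s, ] <- round_preserve_sum(
        rebalance_step(counts[s, ], schedule$dynamic_total,
                       free = !constrained),
        schedule$dynamic_total)
    }
  }
  demand_schedule(counts, schedule$dynamic_total, rownames(counts),
                  schedule$observed)
}

#' Binary transition-rule matrix
#'
#' Rows are the current class, columns the future class; entries are 1
#' (allowed) or 0 (forbidden).  The diagonal must be all 1 — a class may
#' always persist.
#'
#' @param mat Square 0/1 matrix with class-id dimnames.
#' @param period Label of the simulation period the matrix applies to.
#' @return A `transition_matrix`.
#' @export
transition_matrix <- function(mat, period = "") {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat))
  if (!all(mat %in% c(0, 1))) stop("transition matrix entries must be 0 or 1")
  if (any(diag(mat) != 1)) stop("transition matrix diagonal must be all 1 (a class may always persist)")
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat))) {
    stop("transition matrix needs identical row and column class labels")
  }
  structure(list(mat = mat == 1, period = period),
            class = "transition_matrix")
}

#' @rdname transition_matrix
#' @param x A `transition_matrix`.
#' @param from_class,to_class Class ids or names (matched against labels).
#' @return `allowed()` returns a logical.
#' @export
allowed <- function(x, from_class, to_class) {
  stopifnot(inherits(x, "transition_matrix"))
  x$mat[as.character(from_class), as.character(to_class)]
}

#' Read / write a transition matrix CSV
#'
#' CSV layout: first column = current-class labels, remaining columns = future
#' classes, entries 0/1.  Labels are checked against the codebook when given.
#'
#' @param path CSV path.
#' @param period Period label.
#' @param codebook Optional codebook; labels must match its modelled ids (or
#'   names).
#' @return A [transition_matrix()].
#' @export
load_transition_matrix <- function(path, period = "", codebook = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) stop("non-numeric entries in ", path)
  if (!all(mat %in% c(0, 1))) stop("non-binary entries in ", path)
  if (!is.null(codebook)) {
    want <- as.character(modelled_ids(codebook))
    lab <- rownames(mat)
    if (!all(lab %in% want)) {
      lab2 <- tryCatch(as.character(class_id(codebook, lab)),
                       error = function(e) lab)
      if (!setequal(lab2, want)) {
        stop("transition labels in ", path,
             " do not match the codebook's modelled classes")
      }
      rownames(mat) <- colnames(mat) <- lab2
    }
    mat <- mat[want, want, drop = FALSE]
  }
  transition_matrix(mat, period)
}

#' @rdname load_transition_matrix
#' @param x A `transition_matrix`.
#' @export
write_transition_csv <- function(x, path) {
  stopifnot(inherits(x, "transition_matrix"))
  m <- x$mat + 0L
  utils::write.csv(m, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read / write a demand schedule CSV
#'
#' CSV layout: rows = classes (first column the class id), one column per
#' time-step, values = fraction of the dynamic area.  Conversion to cell
#' counts is exact by construction (`dynamic_total` fixed, largest-remainder
#' rounding).
#'
#' @param schedule A [demand_schedule()].
#' @param path CSV path.
#' @export
write_demand_csv <- function(schedule, path) {
  frac <- t(schedule$counts) / schedule$dynamic_total
  out <- data.frame(class = rownames(frac), frac, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_demand_csv
#' @param dynamic_total Number of dynamic cells the fractions refer to.
#' @param observed Logical per step (defaults to all FALSE).
#' @export
read_demand_csv <- function(path, dynamic_total, observed = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  cls <- as.character(tab[[1]])
  frac <- as.matrix(tab[, -1, drop = FALSE])
  counts <- t(apply(t(frac) * dynamic_total, 1,
                    round_preserve_sum, total = dynamic_total))
  colnames(counts) <- cls
  demand_schedule(counts, dynamic_total, colnames(tab)[-1], observed)
}

#' Default Swiss-scenario transition matrices
#'
#' Encodes the baseline scenario rules over the 14 modelled classes as two
#' period matrices: the first applies until the first forecast step, the
#' second from the second step on.  The rules, in brief: urban land (Industry,
#' Building, Special urban, Urban green) can never be taken over; only Arable
#' and Grassland may urbanise, and only in period 1 (urban expansion is
#' prevented afterwards); Arable and Grassland interconvert freely and may
#' take over Forest, Brush and Unproductive vegetation; Alpine grassland may
#' take over Forest, Brush, Trees and Unproductive vegetation, while the
#' successional sequence Alpine grassland -> Brush/Trees -> Forest runs only
#' forest-ward (Forest can never become Trees or Brush); forest expansion is
#' barred from built and cultivated land but allowed on Alpine grassland,
#' Brush, Trees and Unproductive vegetation; Trees, Brush and Unproductive
#' vegetation interconvert, and Trees alone may take over Grassland (hedges);
#' Horticulture may replace Arable, Grassland, Trees or Unproductive
#' vegetation (demand-capped to replacing losses) and may itself revert to
#' Arable or Grassland; deglaciation runs Glacier -> Bare land ->
#' Unproductive vegetation only, with Unproductive vegetation the only class
#' that can take over Bare land, and nothing can become Glacier.
#'
#' @param codebook A codebook with the Swiss classes ([swiss_codebook()]).
#' @return List with `period1` and `period2` [transition_matrix()] objects.
#' @export
default_transition_matrices <- function(codebook = swiss_codebook()) {
  ids <- modelled_ids(codebook)
  id <- function(nm) as.character(class_id(codebook, nm))
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(as.character(ids),
                                        as.character(ids)))
  diag(m) <- 1L
  urban <- id(c("Industry", "Building", "Special urban", "Urban green"))
  horti <- id("Horticulture"); arable <- id("Arable"); grass <- id("Grassland")
  alp <- id("Alpine grassland"); forest <- id("Forest"); brush <- id("Brush")
  trees <- id("Trees"); unprod <- id("Unproductive vegetation")
  bare <- id("Bare land"); glacier <- id("Glacier")

  m[c(arable, grass, trees, unprod), horti] <- 1L   # replacing losses only
  m[horti, c(arable, grass)] <- 1L
  m[arable, grass] <- 1L; m[grass, arable] <- 1L
  m[c(forest, brush, unprod), c(arable, grass)] <- 1L
  m[c(forest, brush, trees, unprod), alp] <- 1L
  m[alp, c(brush, trees, forest)] <- 1L
  m[c(brush, trees, unprod), forest] <- 1L
  m[brush, c(trees, unprod)] <- 1L
  m[trees, c(brush, unprod)] <- 1L
  m[unprod, c(brush, trees)] <- 1L
  m[grass, trees] <- 1L                              # hedges
  m[glacier, bare] <- 1L
  m[bare, unprod] <- 1L

  p1 <- m
  p1[c(arable, grass), urban] <- 1L                  # period-1 urbanisation
  list(period1 = transition_matrix(p1, "period1"),
       period2 = transition_matrix(m, "period2"))
}

#' Default Swiss-scenario demand overrides
#'
#' Urban classes and Horticulture are held at their first-forecast-step value
#' from the second forecast step on.
#'
#' @param codebook Swiss codebook.
#' @param start_step Schedule step (1-based over all steps) the freeze starts
#'   at.
#' @return List of [policy_override()]s.
#' @export
default_policy_overrides <- function(codebook = swiss_codebook(),
                                     start_step) {
  list(policy_override(class_id(codebook,
                                c("Industry", "Building", "Special urban",
                                  "Urban green", "Horticulture")),
                       "freeze", start_step))
}
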