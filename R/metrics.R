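#' Confusion matrix of two class vectors
#'
#' Counts with rows = reference class and columns = predicted class, over a
#' shared class set.
#'
#' @param reference,predicted Equal-length class-code vectors.
#' @param classes Class ids spanning both vectors (default: their union).
#' @return A `confusion_matrix` (square integer matrix with a `prop`
#'   attribute holding counts / total).
#' @export
confusion <- function(reference, predicted, classes = NULL) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted lengths differ")
  }
  if (is.null(classes)) classes <- sort(unique(c(reference, predicted)))
  f <- function(x) factor(x, levels = classes)
  cm <- table(reference = f(reference), predicted = f(predicted))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(reference = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", "matrix"),
            prop = cm / sum(cm))
}

#' Overall accuracy with a normal-approximation confidence interval
#'
#' `oa = trace / total`; the interval is `oa +/- z * sqrt(oa(1-oa)/n)`
#' clipped to `[0, 1]` (a Wilson interval is available by flag, matching the
#' same contract).
#'
#' @param cm A [confusion()] matrix (or plain square count matrix).
#' @param level Confidence level (default 0.95).
#' @param method `"normal"` (default) or `"wilson"`.
#' @return Named vector `(oa, low, high)`.
#' @export
overall_accuracy_ci <- function(cm, level = 0.95,
                                method = c("normal", "wilson")) {
  method <- match.arg(method)
  n <- sum(cm)
  stopifnot(n > 0)
  oa <- sum(diag(cm)) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "normal") {
    half <- z * sqrt(oa * (1 - oa) / n)
    lo <- max(0, oa - half); hi <- min(1, oa + half)
  } else {
    den <- 1 + z^2 / n
    ctr <- (oa + z^2 / (2 * n)) / den
    half <- z * sqrt(oa * (1 - oa) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - half); hi <- min(1, ctr + half)
  }
  c(oa = oa, low = lo, high = hi)
}

#' Quantity and allocation disagreement
#'
#' Pontius-style decomposition of map disagreement.  With `p` the proportion
#' matrix (counts / total), per class `g`:
#' `q_g = |p_{+g} - p_{g+}|` and
#' `a_g = 2 * min(p_{g+} - p_{gg}, p_{+g} - p_{gg})`;
#' `Q = sum(q_g) / 2`, `A = sum(a_g) / 2`, and `Q + A = 1 - overall accuracy`
#' exactly (pre-rounding).
#'
#' @param cm A [confusion()] matrix (or plain square count matrix).
#' @return Named vector `(Q, A)`.
#' @export
quantity_allocation_disagreement <- function(cm) {
  p <- cm / sum(cm)
  rowt <- rowSums(p); colt <- colSums(p)
  q <- abs(colt - rowt)
  a <- 2 * pmin(rowt - diag(p), colt - diag(p))
  c(Q = sum(q) / 2, A = sum(a) / 2)
}

#' Per-class sensitivity, specificity and balanced accuracy
#'
#' One-vs-rest true-positive and true-negative rates per class; balanced
#' accuracy is their mean.  A class absent from the reference has undefined
#' sensitivity and is reported as `NA` (flagged with a warning), never as 0.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with columns `class`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`.
#' @export
per_class_stats <- function(cm) {
  stopifnot(nrow(cm) >= 2)
  n <- sum(cm)
  cls <- rownames(cm)
  tp <- diag(cm)
  ref <- rowSums(cm); pred <- colSums(cm)
  sens <- ifelse(ref > 0, tp / ref, NA_real_)
  tn <- n - ref - pred + tp
  spec <- tn / (n - ref)
  if (anyNA(sens)) {
    warning("class(es) absent from the reference: ",
            paste(cls[is.na(sens)], collapse = ", "),
            "; sensitivity undefined")
  }
  data.frame(class = cls, sensitivity = sens, specificity = spec,
             balanced_accuracy = (sens + spec) / 2, row.names = NULL)
}

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity Numeric vectors.
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Audit of demand satisfaction after allocation
#'
#' Per class and forecast step, the difference between the requested and the
#' obtained prevalence change relative to a baseline map:
#' `(obtained - baseline) - (demanded - baseline) = obtained - demanded`,
#' expressed as a fraction of the dynamic area (a class asked to grow by 0.3
#' that grows by 0.4 scores 0.1).  Classes overridden downstream of the
#' allocation (e.g. Glacier and Bare land after the mechanistic overlay) can
#' be exempted.
#'
#' @param baseline The reference `lulc_map` the requested increases refer to.
#' @param schedule The [demand_schedule()] used for the forecast.
#' @param allocated List of allocated `lulc_map`s, one per future step of the
#'   schedule (in order).
#' @param exempt Class ids excluded from the audit (default none).
#' @return Matrix (steps x classes) of differences as fractions of the
#'   dynamic area.
#' @export
demand_audit <- function(baseline, schedule, allocated, exempt = NULL) {
  fut <- which(!schedule$observed)
  stopifnot(length(allocated) <= length(fut))
  ids <- colnames(schedule$counts)
  base <- observed_prevalence(baseline)[ids]
  out <- matrix(NA_real_, length(allocated), length(ids),
                dimnames = list(rownames(schedule$counts)[fut[seq_along(allocated)]],
                                ids))
  for (s in seq_along(allocated)) {
    obt <- observed_prevalence(allocated[[s]])[ids]
    req <- schedule$counts[fut[s], ids]
    out[s, ] <- ((obt - base) - (req - base)) / schedule$dynamic_total
  }
  if (!is.null(exempt)) out[, !(ids %in% as.character(exempt)), drop = FALSE]
  else out
}

#' Full validation report for a reference/predicted map pair
#'
#' @param reference,predicted Aligned `lulc_map`s (or class vectors).
#' @param level Confidence level for the overall-accuracy interval.
#' @return A `metrics_report` list: `confusion`, `overall` (oa, low, high),
#'   `disagreement` (Q, A) and `per_class`.
#' @export
metrics_report <- function(reference, predicted, level = 0.95) {
  if (inherits(reference, "lulc_map")) {
    stop_if_misaligned(reference$grid, predicted$grid)
    keep <- reference$valid_mask & predicted$valid_mask
    cm <- confusion(reference$codes[keep], predicted$codes[keep],
                    classes = sort(reference$codebook$id))
    present <- rowSums(cm) + colSums(cm) > 0
    cm <- structure(cm[present, present, drop = FALSE],
                    class = c("confusion_matrix", "matrix"))
  } else {
    cm <- confusion(reference, predicted)
  }
  structure(list(confusion = cm,
                 overall = overall_accuracy_ci(cm, level),
                 disagreement = quantity_allocation_disagreement(cm),
                 per_class = per_class_stats(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Map-comparison metrics\n")
  cat(sprintf("  overall accuracy %.*f (95%% CI %.*f-%.*f)\n", digits,
              x$overall["oa"], digits, x$overall["low"], digits,
              x$overall["high"]))
  cat(sprintf("  quantity disagreement %.*f, allocation disagreement %.*f\n",
              digits, x$disagreement["Q"], digits, x$disagreement["A"]))
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], round_half_up, digits = 2)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' Two files: `<stem>_summary.csv` (overall accuracy, CI, Q, A) and
#' `<stem>_classes.csv` (per-class statistics); values at full precision.
#'
#' @param report A `metrics_report`.
#' @param stem Output path stem.
#' @export
write_metrics_csv <- function(report, stem) {
  utils::write.csv(data.frame(metric = c("overall_accuracy", "ci_low",
                                         "ci_high", "quantity_disagreement",
                                         "allocation_disagreement"),
                              value = c(report$overall, report$disagreement)),
                   paste0(stem, "_summary.csv"), row.names = FALSE)
  utils::write.csv(report$per_class, paste0(stem, "_classes.csv"),
                   row.names = FALSE)
  invisible(stem)
}
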