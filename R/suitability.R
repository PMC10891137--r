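#' Suitability model specification
#'
#' Architecture and training contract of the suitability classifier.  The
#' `"mlp"` engine is a feedforward network with exactly five densely
#' connected ReLU hidden layers separated by four dropout layers and a
#' softmax output over the modelled classes; the `"multinom"` engine is the
#' multinomial-logistic fallback ([nnet::multinom()]) used when speed matters
#' more than capacity.  Either engine satisfies the same contract: a feature
#' vector maps to a probability simplex over the modelled classes.
#'
#' @param hidden_sizes Five positive integers (`"mlp"` only; default
#'   256-128-64-32-16, a tapered stack that scales down for toy problems).
#' @param dropout_rate Dropout fraction between hidden layers (default 0.2).
#' @param validation_split Fraction of rows held out for validation
#'   (default 0.2).
#' @param max_epochs Maximum training epochs (default 200; early stopping on
#'   validation loss with `patience` usually ends training earlier).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param batch_size Minibatch size (default 256).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param engine `"mlp"` or `"multinom"`.
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @return A `model_spec`.
#' @export
model_spec <- function(hidden_sizes = c(256, 128, 64, 32, 16),
                       dropout_rate = 0.2, validation_split = 0.2,
                       max_epochs = 200, patience = 10, batch_size = 256,
                       learning_rate = 1e-3,
                       engine = c("mlp", "multinom"), seed = 1) {
  engine <- match.arg(engine)
  if (engine == "mlp" && length(hidden_sizes) != 5) {
    stop("the mlp engine uses exactly five hidden layers")
  }
  stopifnot(all(hidden_sizes >= 1), dropout_rate >= 0, dropout_rate < 1,
            validation_split >= 0, validation_split < 1)
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate,
                 validation_split = validation_split,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 engine = engine, seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit the suitability classifier on a training table
#'
#' Encodes the table under a frozen feature schema (correlation filter,
#' standardisation, one-hot encoding fitted on the non-synthetic rows'
#' change signal), then trains the engine of `spec`.
#'
#' @param table A `training_table` (typically [balanced_change_sample()]
#'   followed by [smote_nc()]).
#' @param spec A [model_spec()].
#' @param codebook The class codebook; the output space is its modelled
#'   classes.
#' @param schema Optional pre-fitted `feature_schema`; fitted from `table`
#'   when omitted.
#' @return An object of class `suitability_model` with the engine fit, the
#'   frozen schema, the modelled class ids and the training history.
#' @export
fit_suitability <- function(table, spec = model_spec(), codebook,
                            schema = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(schema)) {
    real <- !table$synthetic_flag
    feat <- table[real, setdiff(names(table),
                                c("response", "change_flag", "synthetic_flag")),
                  drop = FALSE]
    schema <- fit_feature_schema(copy_types(feat, table),
                                 table$change_flag[real])
  }
  X <- encode_features(schema, table)
  classes <- modelled_ids(codebook)
  y <- table$response
  bad <- setdiff(unique(y), classes)
  if (length(bad)) stop("response contains non-modelled class(es): ",
                        paste(bad, collapse = ", "))
  if (ncol(X) < 1) stop("empty feature matrix")
  fit <- if (spec$engine == "mlp") {
    mlp_fit(X, classes, y, hidden = spec$hidden_sizes,
            dropout_rate = spec$dropout_rate,
            learning_rate = spec$learning_rate,
            batch_size = spec$batch_size, max_epochs = spec$max_epochs,
            validation_split = spec$validation_split,
            patience = spec$patience, seed = spec$seed)
  } else {
    df <- data.frame(.y = factor(y, levels = classes), X, check.names = FALSE)
    fit <- with_seed(spec$seed,
                     nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                    maxit = 300, MaxNWts = 1e5))
    p <- multinom_probs(fit, X, classes)
    hist <- data.frame(epoch = 1L,
                       loss = -mean(log(pmax(p[cbind(seq_along(y),
                                                     match(y, classes))],
                                             1e-12))),
                       accuracy = mean(classes[max.col(p, "first")] == y),
                       val_loss = NA_real_, val_accuracy = NA_real_)
    list(multinom = fit, levels = classes, history = hist, best_epoch = 1L,
         split = list(train = nrow(X), validation = 0L))
  }
  structure(list(engine = spec$engine, fit = fit, spec = spec,
                 schema = schema, classes = classes,
                 n_inputs = ncol(X), history = fit$history),
            class = "suitability_model")
}

copy_types <- function(df, from) {
  attr(df, "types") <- attr(from, "types")[names(df)]
  df
}

multinom_probs <- function(fit, X, classes) {
  p <- stats::predict(fit, newdata = as.data.frame(X, check.names = FALSE),
                      type = "probs")
  if (is.null(dim(p))) {   # two-class multinom returns a vector
    p <- cbind(1 - p, p)
  }
  p <- matrix(p, nrow = nrow(X), dimnames = list(NULL, classes))
  p
}

#' Class-membership probabilities for encoded features
#'
#' @param object A `suitability_model`.
#' @param table Raw feature table with the schema's columns (or a
#'   `training_table`).
#' @param ... Unused.
#' @return Matrix of per-row probabilities over the modelled classes (rows
#'   sum to 1).
#' @export
predict.suitability_model <- function(object, table, ...) {
  X <- encode_features(object$schema, table)
  if (ncol(X) != object$n_inputs) {
    stop(sprintf("feature matrix has %d columns but the model expects %d",
                 ncol(X), object$n_inputs))
  }
  if (object$engine == "mlp") {
    mlp_predict_prob(object$fit, X)
  } else {
    multinom_probs(object$fit$multinom, X, object$classes)
  }
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf("<suitability_model> engine %s, %d inputs -> %d classes\n",
              x$engine, x$n_inputs, length(x$classes)))
  if (x$engine == "mlp") {
    cat(sprintf("  hidden %s, dropout %.2f, best epoch %d/%d\n",
                paste(x$spec$hidden_sizes, collapse = "-"),
                x$spec$dropout_rate, x$fit$best_epoch,
                nrow(x$history)))
  }
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final loss %.4f, accuracy %.4f", h$loss, h$accuracy))
  if (!is.na(h$val_loss)) cat(sprintf(" (val %.4f / %.4f)", h$val_loss,
                                      h$val_accuracy))
  cat("\n")
  invisible(x)
}

#' @export
summary.suitability_model <- function(object, ...) {
  cat("Suitability classifier\n")
  print(object)
  cat(sprintf("  schema: %d continuous retained (|r| < %.2f), %d categorical\n",
              length(object$schema$continuous), object$schema$threshold,
              length(object$schema$categorical)))
  invisible(object$history)
}

#' Per-class suitability stack over a landscape
#'
#' Builds the raw feature table for every dynamic cell of the t0 map
#' (history + predictor stack), encodes it under the model's frozen schema,
#' and lays the engine's class probabilities out as one raster layer per
#' modelled class.  Per valid cell, the layers sum to 1; nodata and static
#' cells are `NA`.
#'
#' @param model A `suitability_model`.
#' @param history List of 3 aligned `lulc_map`s (t-2, t-1, t0).
#' @param stack Aligned [predictor_stack()].
#' @param window_cells Focal window width (defaults to the training table's).
#' @return A `suitability_stack`: list of probability matrices (one per
#'   modelled class id) plus the grid.
#' @export
predict_suitability <- function(model, history, stack, window_cells = 7) {
  table <- build_feature_table(history, stack, window_cells)
  cells <- attr(table, "cells")
  p <- predict(model, table)
  grid <- history[[3]]$grid
  layers <- lapply(seq_along(model$classes), function(j) {
    m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    m[cells] <- p[, j]
    m
  })
  structure(list(layers = stats::setNames(layers, model$classes),
                 classes = model$classes, grid = grid, cells = cells),
            class = "suitability_stack")
}

#' Construct a suitability stack from probability layers
#'
#' Mostly produced by [predict_suitability()]; the constructor lets
#' externally computed membership probabilities enter the allocation stage.
#'
#' @param layers Named list (names = modelled class ids) of probability
#'   matrices; per cell with data, values must sum to 1 over the layers.
#' @param grid The `lulc_grid` the layers live on.
#' @return A `suitability_stack`.
#' @export
suitability_stack <- function(layers, grid) {
  stopifnot(length(layers) >= 2, !is.null(names(layers)))
  for (m in layers) stopifnot(all(dim(m) == c(grid$n_rows, grid$n_cols)))
  classes <- as.integer(names(layers))
  cells <- which(!is.na(layers[[1]]))
  structure(list(layers = layers, classes = classes, grid = grid,
                 cells = cells),
            class = "suitability_stack")
}

#' Autoregressive projection of one time-step
#'
#' Recomputes the LULC-derived features (lagged classes, neighbourhood
#' proportions, dominant class) from the supplied 3-map history, substitutes
#' any time-varying predictor layers (e.g. climate) into the stack, leaves
#' all other features unchanged, and returns the suitability stack for the
#' next step.  After allocating t+1, the next call's history is
#' (t-1, t0, t+1).
#'
#' @param model A `suitability_model`.
#' @param history List of exactly 3 aligned maps (t-2, t-1, t0).
#' @param stack Static predictor stack.
#' @param timestep_predictors Optional named list of layers replacing
#'   same-named stack layers for this step.
#' @param window_cells Focal window width.
#' @return A `suitability_stack` for t+1.
#' @export
project_step <- function(model, history, stack, timestep_predictors = NULL,
                         window_cells = 7) {
  if (length(history) != 3) stop("history must contain exactly 3 maps")
  if (!is.null(timestep_predictors)) {
    unknown <- setdiff(names(timestep_predictors), names(stack$layers))
    if (length(unknown)) stop("time-varying layer(s) not in the stack: ",
                              paste(unknown, collapse = ", "))
    for (nm in names(timestep_predictors)) {
      stack$layers[[nm]] <- timestep_predictors[[nm]]
    }
    stack <- predictor_stack(stack$layers, stack$grid, stack$types)
  }
  predict_suitability(model, history, stack, window_cells)
}

#' Convenience trainer from maps to model
#'
#' Runs the full training pipeline: balanced change sampling on
#' (t-2, t-1, t0) vs the response map, SMOTE-NC augmentation of the changing
#' subset, schema fitting and engine training.
#'
#' @param maps List of >= 4 aligned maps; the last is the response step.
#' @param stack Aligned [predictor_stack()].
#' @param codebook Class codebook.
#' @param spec A [model_spec()].
#' @param window_cells Focal window width.
#' @param smote_k SMOTE-NC neighbour count.
#' @param seed Seed for sampling and augmentation.
#' @return A `suitability_model`.
#' @export
train_suitability <- function(maps, stack, codebook, spec = model_spec(),
                              window_cells = 7, smote_k = 5, seed = 1) {
  n <- length(maps)
  stopifnot(n >= 4)
  tab <- balanced_change_sample(maps[(n - 3):(n - 1)], maps[[n]], stack,
                                window_cells = window_cells, seed = seed)
  tab <- smote_nc(tab, k = smote_k, seed = seed + 1L)
  fit_suitability(tab, spec, codebook)
}
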