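# Shared fixtures, built in code and cached for the duration of one test run.

# the default synthetic landscape (100 x 100, 6 classes, one static)
default_land <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_landscape(landscape_config())
    cache
  }
})

# fast multinomial-logistic suitability model trained on the default landscape
default_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      land <- default_land()
      cache <<- train_suitability(land$maps, land$stack, land$codebook,
                                  model_spec(engine = "multinom", seed = 1),
                                  seed = 1)
    }
    cache
  }
})

# tiny map on an n x m grid from a code matrix
tiny_map <- function(codes, codebook = NULL, cell_size = 100) {
  codes <- as.matrix(codes)
  if (is.null(codebook)) {
    codebook <- synthetic_codebook(max(3, max(codes)))
  }
  lulc_map(codes, lulc_grid(nrow(codes), ncol(codes), cell_size), codebook)
}

# hand-built suitability stack from an ncell x K matrix (row-major cells)
stack_from_matrix <- function(S, grid, classes) {
  layers <- lapply(seq_along(classes), function(j) {
    matrix(S[, j], grid$n_rows, grid$n_cols, byrow = TRUE)
  })
  suitability_stack(stats::setNames(layers, classes), grid)
}

# exhaustive-enumeration oracle: best feasible assignment (max total
# suitability) of n cells to classes under demand counts and rules
enumerate_best <- function(S, cur_k, demand, rules_mat) {
  n <- nrow(S); K <- ncol(S)
  grids <- rep(list(seq_len(K)), n)
  combos <- as.matrix(expand.grid(grids))
  best_val <- -Inf; best <- NULL; n_feasible <- 0L
  for (i in seq_len(nrow(combos))) {
    a <- combos[i, ]
    if (!all(rules_mat[cbind(cur_k, a)])) next
    if (!all(tabulate(a, nbins = K) == demand)) next
    n_feasible <- n_feasible + 1L
    v <- sum(S[cbind(seq_len(n), a)])
    if (v > best_val) { best_val <- v; best <- a }
  }
  list(value = best_val, assignment = best, n_feasible = n_feasible)
}

expect_simplex <- function(S, tol = 1e-6) {
  expect_true(all(S >= -tol & S <= 1 + tol))
  expect_lt(max(abs(rowSums(S) - 1)), tol)
}
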