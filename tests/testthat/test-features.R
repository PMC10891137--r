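test_that("neighbourhood proportions count classes in truncated windows", {
  cb <- synthetic_codebook(3)
  uni <- tiny_map(matrix(3, 5, 5), cb)
  expect_equal(neighbourhood_proportion(uni, 3, 3),
               matrix(1, 5, 5))
  expect_equal(neighbourhood_proportion(uni, 1, 3),
               matrix(0, 5, 5))

  # checkerboard: a 3x3 interior window centred on class A holds 5 A cells
  n <- 9
  cb2 <- synthetic_codebook(3)
  board <- matrix(ifelse((row(matrix(0, n, n)) + col(matrix(0, n, n))) %% 2 == 0,
                         1, 2), n, n)
  m <- tiny_map(board, cb2)
  p1 <- neighbourhood_proportion(m, 1, 3)
  centre <- c(5, 5)  # class 1 cell (5+5 even)
  expect_equal(p1[centre[1], centre[2]], 5 / 9)

  # proportions over all classes sum to 1 on valid cells
  land <- default_land()
  t0 <- land$maps[[1]]
  tot <- Reduce(`+`, lapply(t0$codebook$id, function(c)
    neighbourhood_proportion(t0, c, 7)))
  expect_lt(max(abs(tot[t0$valid_mask] - 1)), 1e-12)
})

test_that("dominant class takes the windowed mode with smallest-id ties", {
  cb <- synthetic_codebook(7)
  uni <- tiny_map(matrix(4, 4, 4), cb)
  expect_true(all(dominant_class(uni, 3) == 4))

  m <- tiny_map(matrix(c(2, 2, 2,
                         2, 2, 7,
                         7, 7, 7), 3, 3, byrow = TRUE), cb)
  expect_equal(dominant_class(m, 3)[2, 2], 2L)   # 5 of class 2, 4 of class 7

  # exact 4/4 tie between classes 3 and 5 with a nodata centre -> 3
  codes <- matrix(c(3, 3, 5,
                    3, 0, 5,
                    3, 5, 5), 3, 3, byrow = TRUE)
  tie <- lulc_map(codes, lulc_grid(3, 3, 100), cb)
  expect_equal(dominant_class(tie, 3)[2, 2], 3L)

  # all-nodata window -> nodata
  empty <- lulc_map(matrix(0, 2, 2), lulc_grid(2, 2, 100), cb)
  expect_true(all(dominant_class(empty, 3) == 0L))
})

test_that("distance_to_class is Euclidean between cell centres", {
  cb <- synthetic_codebook(3)
  codes <- matrix(1, 3, 3); codes[2, 2] <- 2
  m <- tiny_map(codes, cb)
  d <- distance_to_class(m, 2)
  expect_equal(d[2, 2], 0)
  expect_equal(d[1, 2], 100)              # rook neighbour
  expect_equal(d[1, 1], 141.42, tolerance = 0.01 / 141)  # diagonal
  # absent class -> sentinel everywhere
  expect_true(all(distance_to_class(m, 3) == 1e7))
  expect_true(all(distance_to_class(m, 3, sentinel = 42) == 42))
})

test_that("one-hot encoding partitions valid cells and freezes its schema", {
  x <- c(2, 5, 9, 5, 2)
  oh <- one_hot(x, prefix = "g")
  expect_equal(colnames(oh), c("g_2", "g_5", "g_9"))
  expect_true(all(rowSums(oh) == 1))

  single <- one_hot(c(4, 4), prefix = "s")
  expect_equal(ncol(single), 1)
  expect_true(all(single == 1))

  expect_error(one_hot(c(2, 5, 7), levels = c(2, 5), prefix = "g"),
               "frozen encoding schema")
})

test_that("the correlation filter keeps the better-ranked of correlated pairs", {
  set.seed(42)
  n <- 1000
  a <- rnorm(n)
  b <- a + rnorm(n, sd = 0.1)   # r ~ 0.99
  c <- rnorm(n)
  x <- cbind(A = a, B = b, C = c)

  # duplicated column: exactly one survives
  kept <- select_uncorrelated(cbind(A = a, A2 = a), c(A = 0.5, A2 = 0.4), 0.7)
  expect_equal(kept, "A")

  # independent columns both survive at 0.7
  kept <- select_uncorrelated(cbind(A = a, C = c), c(A = 0.3, C = 0.2), 0.7)
  expect_setequal(kept, c("A", "C"))

  # A ~ B: the better-ranked of the pair plus the independent column
  kept <- select_uncorrelated(x, c(A = 0.2, B = 0.6, C = 0.4), 0.7)
  expect_setequal(kept, c("B", "C"))

  # ranking defines order: permuting the input columns changes nothing
  kept2 <- select_uncorrelated(x[, c(3, 1, 2)], c(C = 0.4, A = 0.2, B = 0.6),
                               0.7)
  expect_setequal(kept2, kept)

  expect_warning(select_uncorrelated(cbind(A = a, Z = rep(1, n)),
                                     c(A = 0.5, Z = 0)), "zero-variance")
})

test_that("standardisation is fitted once and applied with stored parameters", {
  sc <- fit_scaler(cbind(x = c(1, 2, 3)))
  expect_equal(as.vector(apply_scaler(sc, cbind(x = c(1, 2, 3)))),
               c(-1, 0, 1))
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  sc <- fit_scaler(x)
  z <- apply_scaler(sc, x)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  y <- matrix(rnorm(40, 5), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  expect_equal(apply_scaler(sc, y),
               sweep(sweep(y, 2, sc$mean), 2, sc$sd, "/"))
})

test_that("the schema standardises continuous columns but leaves indicators binary", {
  land <- default_land()
  tab <- balanced_change_sample(land$maps[1:3], land$maps[[4]], land$stack,
                                seed = 1)
  feat_cols <- setdiff(names(tab), c("response", "change_flag", "synthetic_flag"))
  feat <- tab[, feat_cols]
  attr(feat, "types") <- attr(tab, "types")[feat_cols]
  schema <- fit_feature_schema(feat, tab$change_flag)
  X <- encode_features(schema, tab)
  oh_cols <- grep("^(lulc_|dominant_|region_)", colnames(X), value = TRUE)
  expect_gt(length(oh_cols), 0)
  expect_true(all(X[, oh_cols] %in% c(0, 1)))
  cont <- X[, schema$continuous, drop = FALSE]
  expect_lt(max(abs(colMeans(cont))), 1e-9)
  # each categorical's one-hot block sums to one per row
  for (v in schema$categorical) {
    block <- X[, grep(paste0("^", v, "_"), colnames(X)), drop = FALSE]
    expect_true(all(rowSums(block) == 1))
  }
})
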