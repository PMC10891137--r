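test_that("confusion matrices count reference x predicted pairs", {
  v <- c(1, 1, 2, 3, 3, 3)
  cm <- confusion(v, v)
  expect_equal(unname(diag(cm)), c(2L, 1L, 3L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  ref <- rep(c(1, 2), times = c(50, 50))
  prd <- c(rep(1, 40), rep(2, 10), rep(2, 50))
  cm2 <- confusion(ref, prd)
  expect_equal(unname(cm2), rbind(c(40L, 10L), c(0L, 50L)),
               ignore_attr = TRUE)
  expect_equal(sum(cm2), length(ref))
  expect_error(confusion(1:3, 1:4), "lengths differ")
})

test_that("the overall-accuracy interval follows the normal approximation", {
  perfect <- confusion(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(unname(overall_accuracy_ci(perfect)), c(1, 1, 1))

  ref <- rep(c(1, 2), each = 50)
  prd <- ref; prd[c(1:10, 51:60)] <- 3 - ref[c(1:10, 51:60)]
  cm <- confusion(ref, prd)      # oa = 0.8, n = 100
  ci <- overall_accuracy_ci(cm)
  half <- stats::qnorm(0.975) * sqrt(0.8 * 0.2 / 100)
  expect_equal(unname(ci), c(0.8, 0.8 - half, 0.8 + half))
  expect_equal(half, 0.0784, tolerance = 1e-3)

  # width shrinks as 1/sqrt(n)
  cm4 <- confusion(rep(ref, 4), rep(prd, 4))
  ci4 <- overall_accuracy_ci(cm4)
  expect_equal((ci4["high"] - ci4["low"]) * 2, ci["high"] - ci["low"],
               tolerance = 1e-12, ignore_attr = TRUE)

  # the Wilson flag stays inside [0, 1] near the boundary
  w <- overall_accuracy_ci(perfect, method = "wilson")
  expect_true(w["low"] < 1 && w["high"] <= 1)
})

test_that("quantity/allocation disagreement matches the closed form", {
  qa <- quantity_allocation_disagreement(rbind(c(40, 10), c(0, 50)))
  expect_equal(unname(qa), c(0.10, 0.00))
  qa2 <- quantity_allocation_disagreement(rbind(c(40, 10), c(10, 40)))
  expect_equal(unname(qa2), c(0.00, 0.20))
})

test_that("Q + A equals total disagreement on arbitrary matrices", {
  with_seed(123, {
    for (i in 1:200) {
      K <- sample(2:6, 1)
      cm <- matrix(stats::rpois(K * K, lambda = sample(1:30, 1)), K, K)
      if (sum(cm) == 0) cm[1, 1] <- 1
      qa <- quantity_allocation_disagreement(cm)
      oa <- sum(diag(cm)) / sum(cm)
      expect_equal(unname(qa["Q"] + qa["A"]), 1 - oa, tolerance = 1e-12)
      expect_true(all(qa >= -1e-12))
    }
  })
})

test_that("metrics are invariant to simultaneous class permutation", {
  with_seed(9, cm <- matrix(stats::rpois(16, 20), 4, 4,
                            dimnames = list(1:4, 1:4)))
  perm <- c(3, 1, 4, 2)
  cmp <- cm[perm, perm]
  expect_equal(quantity_allocation_disagreement(cm),
               quantity_allocation_disagreement(cmp))
  expect_equal(overall_accuracy_ci(cm), overall_accuracy_ci(cmp))
  a <- per_class_stats(structure(cm, class = c("confusion_matrix", "matrix")))
  b <- per_class_stats(structure(cmp, class = c("confusion_matrix", "matrix")))
  expect_equal(a$balanced_accuracy[perm], b$balanced_accuracy)
})

test_that("per-class statistics give one-vs-rest rates with NA for absent classes", {
  cm <- confusion(rep(c(1, 2), each = 50),
                  c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40)))
  st <- per_class_stats(cm)
  expect_equal(st$sensitivity, c(0.8, 0.8))
  expect_equal(st$specificity, c(0.8, 0.8))
  expect_equal(st$balanced_accuracy, c(0.8, 0.8))

  perfect <- confusion(1:3, 1:3)
  expect_true(all(per_class_stats(perfect)$balanced_accuracy == 1))

  # class 3 in the codebook but absent from the reference
  cm3 <- confusion(c(1, 1, 2), c(1, 3, 2), classes = 1:3)
  expect_warning(st3 <- per_class_stats(cm3), "absent from the reference")
  expect_true(is.na(st3$sensitivity[3]))
  expect_true(is.na(st3$balanced_accuracy[3]))
  expect_false(is.na(st3$specificity[3]))
})

test_that("balanced accuracy reproduces the published class table arithmetic", {
  tab <- utils::read.csv(system.file("extdata", "swiss_nn_class_stats.csv",
                                     package = "lucsim"))
  ba <- balanced_accuracy(tab$sensitivity, tab$specificity)
  expect_equal(round_half_up(ba[tab$class == 12], 2), 0.72)
  expect_equal(round_half_up(ba[tab$class == 3], 2), 0.81)
  expect_equal(round_half_up(mean(ba), 2), 0.89)
  expect_equal(tab$class[which.max(ba)], 9)   # Forest scores highest
})

test_that("the demand audit reports obtained minus requested prevalence change", {
  cb <- synthetic_codebook(3)
  base <- tiny_map(matrix(rep(c(1, 2), c(60, 40)), 10, 10), cb)
  alloc <- tiny_map(matrix(rep(c(1, 2), c(70, 30)), 10, 10), cb)
  counts <- rbind(c(60, 40, 0), c(65, 35, 0))
  colnames(counts) <- 1:3
  sched <- demand_schedule(counts, 100, observed = c(TRUE, FALSE))
  aud <- demand_audit(base, sched, list(alloc))
  # requested +5 for class 1, obtained +10 -> difference +0.05 of the area
  expect_equal(unname(aud[1, ]), c(0.05, -0.05, 0))
  # allocation exactly meeting demand -> all zeros
  exact <- tiny_map(matrix(rep(c(1, 2), c(65, 35)), 10, 10), cb)
  expect_true(all(demand_audit(base, sched, list(exact)) == 0))
})
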