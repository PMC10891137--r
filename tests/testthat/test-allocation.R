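perm_rules <- function(K) {
  ids <- as.character(seq_len(K))
  transition_matrix(matrix(1L, K, K, dimnames = list(ids, ids)), "all")
}

test_that("demand equal to the argmax counts converges immediately with zero lambda", {
  grid <- lulc_grid(2, 2, 100)
  cb <- synthetic_codebook(3)   # classes 1..3 all modelled; use 2 in stack
  S <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.4, 0.6), c(0.3, 0.7))
  suit <- stack_from_matrix(cbind(S, 0) / rowSums(cbind(S, 0)), grid, 1:3)
  # renormalised to a 3-simplex: class 3 gets 0 everywhere
  cur <- tiny_map(matrix(1, 2, 2), cb)
  res <- clues_allocate(suit, cur, c(`1` = 2, `2` = 2, `3` = 0),
                        perm_rules(3), tolerance = 0)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_true(all(res$lambda == 0))
  expect_equal(unname(res$deviation), rep(0, 3))
})

test_that("the worked four-cell instance allocates by suitability rank", {
  grid <- lulc_grid(1, 4, 100)
  cb <- synthetic_codebook(3)
  S3 <- cbind(rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.4, 0.6), c(0.3, 0.7)), 0)
  suit <- stack_from_matrix(S3, grid, 1:3)
  cur <- tiny_map(matrix(2, 1, 4), cb)
  res <- clues_allocate(suit, cur, c(`1` = 2, `2` = 2, `3` = 0),
                        perm_rules(3), tolerance = 0)
  expect_true(res$converged)
  expect_equal(as.vector(res$map$codes), c(1, 1, 2, 2))

  # the same assignment maximises total suitability over all feasible ones
  oracle <- enumerate_best(S3, rep(2L, 4), c(2, 2, 0),
                           matrix(TRUE, 3, 3))
  got <- sum(S3[cbind(1:4, as.vector(res$map$codes))])
  expect_equal(got, oracle$value)
})

test_that("diagonal-only rows pin cells and competition respects the rules", {
  grid <- lulc_grid(1, 4, 100)
  cb <- synthetic_codebook(3)
  S3 <- cbind(rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.4, 0.6), c(0.3, 0.7)), 0)
  suit <- stack_from_matrix(S3, grid, 1:3)
  # cell 3's current class (1) may only persist
  cur <- tiny_map(matrix(c(2, 2, 1, 2), 1, 4), cb)
  ids <- as.character(1:3)
  m <- matrix(1L, 3, 3, dimnames = list(ids, ids))
  m[1, c(2, 3)] <- 0L
  rules <- transition_matrix(m, "p")
  res <- clues_allocate(suit, cur, c(`1` = 2, `2` = 2, `3` = 0), rules,
                        tolerance = 0)
  expect_true(res$converged)
  expect_equal(res$map$codes[1, 3], 1L)   # pinned by the rules
  # remaining demand (1 more class 1, 2 class 2) falls on cells 1, 2, 4:
  # cell 1 has the highest class-1 suitability
  expect_equal(as.vector(res$map$codes), c(1, 2, 1, 2))
})

test_that("infeasible demand under the rules is reported with the class", {
  grid <- lulc_grid(1, 3, 100)
  cb <- synthetic_codebook(3)
  S3 <- matrix(1 / 3, 3, 3)
  suit <- stack_from_matrix(S3, grid, 1:3)
  cur <- tiny_map(matrix(2, 1, 3), cb)
  ids <- as.character(1:3)
  m <- matrix(0L, 3, 3, dimnames = list(ids, ids)); diag(m) <- 1L
  m[2, 3] <- 1L
  # nothing may become class 1, yet demand asks for one cell of it
  expect_error(clues_allocate(suit, cur, c(`1` = 1, `2` = 2, `3` = 0),
                              transition_matrix(m, "p"), tolerance = 0),
               "infeasible.*1")
})

test_that("non-simplex suitability and mismatched demand are rejected", {
  grid <- lulc_grid(1, 2, 100)
  cb <- synthetic_codebook(3)
  bad <- stack_from_matrix(rbind(c(0.9, 0.9, 0), c(0.1, 0.1, 0)), grid, 1:3)
  cur <- tiny_map(matrix(1, 1, 2), cb)
  expect_error(clues_allocate(bad, cur, c(`1` = 1, `2` = 1, `3` = 0),
                              perm_rules(3)), "simplex")
  ok <- stack_from_matrix(rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), grid, 1:3)
  expect_error(clues_allocate(ok, cur, c(`1` = 5, `2` = 1, `3` = 0),
                              perm_rules(3)), "dynamic cells")
})

test_that("converged allocations match the exhaustive oracle on small instances", {
  for (s in 1:8) {
    n <- 6 + (s %% 4)          # 6..9 cells
    K <- 2 + (s %% 2)          # 2..3 classes
    with_seed(300 + s, {
      S <- matrix(stats::runif(n * K), n, K)
      S <- S / rowSums(S)
      demand <- as.vector(stats::rmultinom(1, n, rep(1, K)))
    })
    grid <- lulc_grid(1, n, 100)
    cb <- synthetic_codebook(max(K, 3))
    Sfull <- if (K == 2) cbind(S, 0) else S
    suit <- stack_from_matrix(Sfull, grid, seq_len(max(K, 3)))
    dem <- stats::setNames(c(demand, rep(0, max(K, 3) - K)),
                           seq_len(max(K, 3)))
    cur <- tiny_map(matrix(rep_len(seq_len(K), n), 1, n), cb)
    res <- clues_allocate(suit, cur, dem, perm_rules(max(K, 3)),
                          tolerance = 0, max_iter = 2000)
    expect_true(res$converged)
    oracle <- enumerate_best(Sfull, rep_len(seq_len(K), n),
                             c(demand, rep(0, max(K, 3) - K)),
                             matrix(TRUE, max(K, 3), max(K, 3)))
    got <- sum(Sfull[cbind(seq_len(n), as.vector(res$map$codes))])
    expect_equal(got, oracle$value, tolerance = 1e-9)
  }
})

test_that("multi-step forecasts conserve cells, respect rules and meet demand", {
  land <- default_land()
  model <- default_model()
  obs <- t(sapply(land$maps, observed_prevalence))
  sched <- extrapolate_demand(obs, 3)
  ids <- modelled_ids(land$codebook)
  rules <- perm_rules(length(ids))
  fc <- run_forecast(model, land$maps[2:4], land$stack, sched, rules)
  expect_length(fc$maps, 3)
  prev_map <- land$maps[[4]]
  for (s in 1:3) {
    m <- fc$maps[[s]]
    # conservation: dynamic-cell count constant, static cells untouched
    expect_equal(sum(dynamic_mask(m)), land$truth$n_dynamic)
    static <- which(prev_map$codes %in% static_ids(land$codebook))
    expect_identical(m$codes[static], prev_map$codes[static])
    # legality (all-permissive here, so just class-space closure)
    expect_true(all(m$codes[dynamic_mask(m)] %in% ids))
    # demand satisfied within tolerance
    expect_true(fc$results[[s]]$converged)
    expect_lte(max(abs(fc$results[[s]]$deviation)),
               max(1, 5e-4 * land$truth$n_dynamic))
    prev_map <- m
  }
  # determinism: a rerun reproduces the sequence exactly
  fc2 <- run_forecast(model, land$maps[2:4], land$stack, sched, rules)
  for (s in 1:3) expect_identical(fc$maps[[s]]$codes, fc2$maps[[s]]$codes)

  # self-consistency: demand fixed at current prevalence keeps deviations tiny
  fixed <- demand_schedule(rbind(obs[4, ], obs[4, ], obs[4, ]),
                           sum(obs[4, ]),
                           observed = c(TRUE, FALSE, FALSE))
  fcf <- run_forecast(model, land$maps[2:4], land$stack, fixed, rules)
  for (r in fcf$results) {
    expect_lte(max(abs(r$deviation)) / land$truth$n_dynamic, 5e-4)
  }
})

test_that("restrictive rules are honoured at every step", {
  land <- default_land()
  model <- default_model()
  ids <- modelled_ids(land$codebook)
  lab <- as.character(ids)
  # forbid everything except persistence and moves into class 1
  m <- matrix(0L, length(ids), length(ids), dimnames = list(lab, lab))
  diag(m) <- 1L
  m[, "1"] <- 1L
  rules <- transition_matrix(m, "restrictive")
  # feasible under these rules: class 1 grows, every other class shrinks
  cur <- observed_prevalence(land$maps[[4]])
  dem <- cur
  dem[lab != "1"] <- dem[lab != "1"] - 10L
  dem["1"] <- dem["1"] + 10L * sum(lab != "1")
  sched <- demand_schedule(rbind(cur, dem), sum(cur),
                           observed = c(TRUE, FALSE))
  fc <- run_forecast(model, land$maps[2:4], land$stack, sched, rules,
                     n_steps = 1)
  from <- land$maps[[4]]$codes
  to <- fc$maps[[1]]$codes
  dyn <- dynamic_mask(land$maps[[4]])
  moved <- dyn & (from != to)
  expect_true(all(to[moved] == 1L))
})
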