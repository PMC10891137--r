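test_that("observed prevalence counts dynamic cells exactly", {
  cb <- synthetic_codebook(6, static_ids = 6)
  uni <- tiny_map(matrix(6 - 5, 10, 10), cb)   # all class 1
  p <- observed_prevalence(uni)
  expect_equal(unname(p[as.character(1)]), 100L)
  expect_equal(sum(p), 100L)

  # planted counts recovered exactly
  codes <- matrix(rep(c(1, 2, 3, 4, 5), times = c(30, 25, 20, 15, 10)), 10, 10)
  m <- tiny_map(codes, cb)
  expect_equal(unname(observed_prevalence(m)), c(30L, 25L, 20L, 15L, 10L))

  land <- default_land()
  for (mp in land$maps) {
    expect_equal(sum(observed_prevalence(mp)), land$truth$n_dynamic)
  }
})

test_that("demand extrapolation continues the last observed slope", {
  obs <- rbind(c(100, 100, 100), c(100, 100, 100),
               c(100, 100, 100), c(100, 100, 100))
  colnames(obs) <- 1:3
  sched <- extrapolate_demand(obs, 3)
  expect_true(all(sched$counts[5:7, ] == 100))

  obs2 <- rbind(c(100, 200), c(120, 180))
  colnames(obs2) <- 1:2
  sched2 <- extrapolate_demand(obs2, 3)
  expect_equal(unname(sched2$counts[3:5, "1"]), c(140, 160, 180))
  expect_equal(unname(rowSums(sched2$counts)), rep(300, 5))

  # negative projection clamps to zero, surplus goes to the others
  obs3 <- rbind(c(30, 70), c(10, 90))
  colnames(obs3) <- 1:2
  sched3 <- extrapolate_demand(obs3, 2)
  expect_equal(unname(sched3$counts[4, "1"]), 0)
  expect_equal(unname(sched3$counts[4, "2"]), 100)
  expect_true(all(sched3$counts >= 0))
})

test_that("policy overrides pin classes and conserve the total", {
  obs <- rbind(c(500, 300, 200), c(500, 320, 180))
  colnames(obs) <- 1:3
  sched <- extrapolate_demand(obs, 3)
  ov <- policy_override(2, "freeze", start_step = 4)
  out <- apply_policy_overrides(sched, ov)
  expect_equal(unname(out$counts[4:5, "2"]),
               rep(unname(sched$counts[3, "2"]), 2))
  expect_equal(unname(rowSums(out$counts)), rep(1000, 5))
  # idempotent
  again <- apply_policy_overrides(out, ov)
  expect_equal(again$counts, out$counts)
  # no overrides: identity
  expect_equal(apply_policy_overrides(sched, list())$counts, sched$counts)

  # replacement-only caps but does not pin
  ov2 <- policy_override(2, "replacement-only", start_step = 4)
  out2 <- apply_policy_overrides(sched, ov2)
  expect_true(all(out2$counts[4:5, "2"] <= sched$counts[3, "2"]))

  # capping every class below the total leaves no class to absorb the
  # residual: infeasible
  ov3 <- policy_override(1:3, "replacement-only", start_step = 2)
  cnts <- rbind(c(500, 300, 200), c(400, 400, 200))
  colnames(cnts) <- 1:3
  sched_u <- demand_schedule(cnts, 1000, observed = c(TRUE, FALSE))
  expect_error(apply_policy_overrides(sched_u, ov3), "infeasible")
})

test_that("transition matrices are validated and queried by label", {
  ids <- as.character(1:3)
  m <- matrix(1, 3, 3, dimnames = list(ids, ids))
  tm <- transition_matrix(m, "p1")
  expect_true(allowed(tm, 1, 2))
  m2 <- m; m2[1, 1] <- 0
  expect_error(transition_matrix(m2), "diagonal")
  m3 <- m; m3[1, 2] <- 0.5
  expect_error(transition_matrix(m3), "0 or 1")

  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.csv")
  m4 <- m; m4[2, 1] <- 0
  write_transition_csv(transition_matrix(m4, "p"), p)
  back <- load_transition_matrix(p, "p")
  expect_equal(back$mat, m4 == 1)
  writeLines("a,b\n1,0.5", file.path(dir, "bad.csv"))
  expect_error(load_transition_matrix(file.path(dir, "bad.csv")), "")
})

test_that("demand CSV round trip preserves counts through fractions", {
  obs <- rbind(c(600, 250, 150), c(580, 260, 160))
  colnames(obs) <- 1:3
  sched <- extrapolate_demand(obs, 2)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "demand.csv")
  write_demand_csv(sched, p)
  back <- read_demand_csv(p, sched$dynamic_total,
                          observed = sched$observed)
  expect_equal(unname(back$counts), unname(sched$counts), tolerance = 1e-6)
})

test_that("the default matrices encode every scenario rule", {
  cb <- swiss_codebook()
  tms <- default_transition_matrices(cb)
  p1 <- tms$period1; p2 <- tms$period2
  id <- function(nm) class_id(cb, nm)
  urban <- id(c("Industry", "Building", "Special urban", "Urban green"))
  all_m <- modelled_ids(cb)

  # 1. no class can take over urban land: urban rows are diagonal-only
  for (u in urban) {
    for (tm in list(p1, p2)) {
      expect_true(all(!tm$mat[as.character(u),
                              as.character(setdiff(all_m, u))]))
    }
  }
  # 2. urban expansion is allowed in period 1 only for Arable and Grassland...
  for (u in urban) {
    expect_true(all(allowed(p1, id(c("Arable", "Grassland")), u)))
    expect_true(all(!allowed(p1, setdiff(all_m, c(id(c("Arable", "Grassland")), u)), u)))
  }
  # 3. ...and prevented entirely in period 2 (urban columns diagonal-only)
  for (u in urban) {
    expect_true(all(!p2$mat[as.character(setdiff(all_m, u)),
                            as.character(u)]))
  }
  # 4. Arable and Grassland interconvert and may take Forest, Brush,
  #    Unproductive vegetation
  for (tm in list(p1, p2)) {
    expect_true(allowed(tm, id("Arable"), id("Grassland")))
    expect_true(allowed(tm, id("Grassland"), id("Arable")))
    expect_true(all(allowed(tm, id(c("Forest", "Brush",
                                     "Unproductive vegetation")),
                            id("Arable"))))
    expect_true(all(allowed(tm, id(c("Forest", "Brush",
                                     "Unproductive vegetation")),
                            id("Grassland"))))
  }
  # 5. Alpine grassland takes Forest, Brush, Trees, Unproductive vegetation;
  #    succession runs forest-ward only (Forest never to Trees or Brush)
  expect_true(all(allowed(p2, id(c("Forest", "Brush", "Trees",
                                   "Unproductive vegetation")),
                          id("Alpine grassland"))))
  expect_true(all(allowed(p2, id("Alpine grassland"),
                          id(c("Brush", "Trees", "Forest")))))
  expect_false(any(allowed(p2, id("Forest"), id(c("Trees", "Brush")))))
  # 6. forest expansion barred from built and cultivated land, allowed on
  #    Alpine grassland, Brush, Trees, Unproductive vegetation
  expect_false(any(allowed(p2, c(urban, id(c("Horticulture", "Arable",
                                             "Grassland"))), id("Forest"))))
  expect_true(all(allowed(p2, id(c("Alpine grassland", "Brush", "Trees",
                                   "Unproductive vegetation")),
                          id("Forest"))))
  # 7. Trees, Brush and Unproductive vegetation interconvert; Trees alone
  #    may take over Grassland (hedges)
  tbu <- id(c("Trees", "Brush", "Unproductive vegetation"))
  for (a in tbu) for (b in tbu) expect_true(allowed(p2, a, b))
  expect_true(allowed(p2, id("Grassland"), id("Trees")))
  expect_false(any(allowed(p2, id("Grassland"), id(c("Forest", "Brush")))))
  # 8. Horticulture replaces Arable, Grassland, Trees, Unproductive
  #    vegetation and may itself revert to Arable or Grassland
  expect_true(all(allowed(p2, id(c("Arable", "Grassland", "Trees",
                                   "Unproductive vegetation")),
                          id("Horticulture"))))
  expect_true(all(allowed(p2, id("Horticulture"), id(c("Arable", "Grassland")))))
  # 9. deglaciation sequence Glacier -> Bare land -> Unproductive vegetation,
  #    one-way; Unproductive vegetation is the only class taking Bare land
  expect_true(allowed(p2, id("Glacier"), id("Bare land")))
  expect_true(allowed(p2, id("Bare land"), id("Unproductive vegetation")))
  expect_false(allowed(p2, id("Bare land"), id("Glacier")))
  expect_false(allowed(p2, id("Unproductive vegetation"), id("Bare land")))
  expect_true(all(!p2$mat[as.character(setdiff(all_m, id(c("Glacier",
                                                           "Bare land")))),
                          as.character(id("Bare land"))]))
  # 10. nothing can ever become Glacier
  for (tm in list(p1, p2)) {
    expect_true(all(!tm$mat[as.character(setdiff(all_m, id("Glacier"))),
                            as.character(id("Glacier"))]))
  }
  # aliases resolve: Orchard == Horticulture, Bare rock == Bare land
  expect_equal(class_id(cb, "Orchard"), id("Horticulture"))
  expect_equal(class_id(cb, "Bare rock"), id("Bare land"))
})
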