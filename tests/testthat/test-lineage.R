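make_table <- function(...) {
  df <- rbind(...)
  data.frame(frame = df[, 1], time_h = df[, 1] * 0.25, cell_id = df[, 2],
             parent_id = ifelse(df[, 3] < 0, NA_integer_, df[, 3]),
             length_um = df[, 4], new_pole_end = "unknown")
}

test_that("a single division yields one root and two leaves", {
  ct <- make_table(
    c(0, 1, -1, 3), c(1, 1, -1, 4),
    c(2, 2, 1, 2.2), c(2, 3, 1, 1.8)
  )
  tree <- build_lineage(ct)
  expect_identical(tree$roots, 1)
  expect_setequal(tree$children[["1"]], c(2, 3))
  expect_length(tree$inconsistencies, 0)
})

test_that("an orphan daughter becomes a root with a warning", {
  ct <- make_table(c(0, 5, 99, 3))
  expect_warning(tree <- build_lineage(ct), "absent parent")
  expect_identical(tree$roots, 5)
})

test_that("a division with a single daughter is flagged", {
  ct <- make_table(c(0, 1, -1, 4), c(1, 2, 1, 2.2))
  expect_warning(tree <- build_lineage(ct), "expected 2")
  expect_length(tree$inconsistencies, 1)
})

test_that("synthetic lineage tree is isomorphic to ground-truth divisions", {
  sim <- simulate_lineage(sim_params(seed = 7), 3)
  tree <- build_lineage(sim$cells)
  dv <- sim$truth$divisions
  expect_identical(length(tree$children), nrow(dv))
  for (i in seq_len(nrow(dv))) {
    expect_setequal(tree$children[[as.character(dv$parent_id[i])]],
                    c(dv$daughter_new_pole_side[i],
                      dv$daughter_old_pole_side[i]))
  }
})

test_that("growth rate is exact on exact exponential data", {
  t <- seq(0, 2, by = 0.25)
  gr <- growth_rate(t, 2 * exp(0.3 * t))
  expect_equal(gr$rate, 0.3, tolerance = 1e-12)
  expect_equal(growth_rate(t, rep(3.5, length(t)))$rate, 0,
               tolerance = 1e-12)
})

test_that("growth rate is invariant to rescaling all lengths", {
  t <- seq(0, 5, by = 0.25)
  set.seed(8)
  lens <- 2 * exp(0.25 * t) * exp(rnorm(length(t), 0, 0.02))
  expect_equal(growth_rate(t, lens)$rate, growth_rate(t, 7 * lens)$rate)
})

test_that("noisy growth rate lands within 3 standard errors of truth", {
  t <- seq(0, by = 0.25, length.out = 30)
  set.seed(15)
  for (r in c(0.15, 0.3)) {
    lens <- 2.2 * exp(r * t) * exp(rnorm(30, 0, 0.02))
    gr <- growth_rate(t, lens)
    expect_lt(abs(gr$rate - r), 3 * gr$se)
  }
})

test_that("growth rate is undefined below 3 frames", {
  expect_true(is.na(growth_rate(c(0, 0.25), c(2, 2.1))$rate))
})

test_that("doubling time is birth-to-division, missing when unobserved", {
  ct <- make_table(
    rbind(cbind(0:12, 1, -1, 2 * exp(0.23 * 0.25 * 0:12))),
    c(13, 2, 1, 1.5), c(13, 3, 1, 1.6)
  )
  tree <- build_lineage(ct)
  # root birth unobserved -> NA even though it divides
  expect_true(is.na(doubling_time(tree, 1)))
  # leaves never divide -> NA
  expect_true(is.na(doubling_time(tree, 2)))
})

test_that("doubling times on synthetic data match ground-truth divisions", {
  sim <- simulate_lineage(sim_params(seed = 7), 3)
  tree <- build_lineage(sim$cells)
  dv <- sim$truth$divisions
  gen2 <- dv$parent_id[dv$parent_id != 1L]  # born and dividing in-movie
  for (id in gen2) {
    born <- min(sim$cells$time_h[sim$cells$cell_id == id])
    died <- sim$cells$time_h[sim$cells$cell_id == id &
                               sim$cells$frame == dv$frame[dv$parent_id == id]]
    expect_equal(doubling_time(tree, id), died - born)
  }
})

test_that("polarity assignment puts the new pole at the division plane", {
  ct <- make_table(c(0, 1, -1, 4), c(1, 2, 1, 2.2), c(1, 3, 1, 1.8))
  tree <- build_lineage(ct)
  tree <- assign_polarity(tree, data.frame(cell_id = c(2, 3),
                                           side = c("left", "right")))
  expect_identical(unique(tree$cells$new_pole_end[tree$cells$cell_id == 2]),
                   "right")
  expect_identical(unique(tree$cells$new_pole_end[tree$cells$cell_id == 3]),
                   "left")
  expect_identical(unique(tree$cells$new_pole_end[tree$cells$cell_id == 1]),
                   "unknown")
})

test_that("synthetic polarity labels agree with division geometry", {
  sim <- simulate_lineage(sim_params(seed = 11), 3)
  tree <- build_lineage(sim$cells)
  non_roots <- setdiff(unique(sim$cells$cell_id), tree$roots)
  expect_true(all(sim$cells$new_pole_end[sim$cells$cell_id %in% non_roots]
                  %in% c("left", "right")))
})

test_that("minicell cutoff is inclusive at the boundary", {
  expect_true(classify_minicell(2.25))
  expect_false(classify_minicell(2.26))
  expect_true(classify_minicell(1.0))
  expect_identical(classify_minicell(c(2.0, 3.0), max_um = 2.25),
                   c(TRUE, FALSE))
})

test_that("cell statistics table covers every cell with coherent values", {
  sim <- simulate_lineage(sim_params(seed = 7), 3)
  tree <- build_lineage(sim$cells)
  st <- cell_statistics(tree)
  expect_identical(sort(st$cell_id), sort(unique(sim$cells$cell_id)))
  grown <- st[!is.na(st$growth_rate), ]
  expect_true(all(abs(grown$growth_rate - 0.23) < 1e-9))
  expect_true(all(st$birth_length_um > 0))
})
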