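test_that("sibling attributes sum and maximise the birth-frame profiles", {
  ct <- data.frame(
    frame = c(0, 1, 1), time_h = c(0, 0.25, 0.25),
    cell_id = c(1, 2, 3), parent_id = c(NA, 1, 1),
    length_um = c(4, 2.4, 1.6), new_pole_end = c("unknown", "right", "left"))
  tree <- build_lineage(ct)
  profiles <- rbind(
    data.frame(cell_id = 2, frame = 1, pixel_index = 0:2,
               parA_intensity = c(1, 2, 3), parB_intensity = 0),
    data.frame(cell_id = 3, frame = 1, pixel_index = 0:1,
               parA_intensity = c(4, 4), parB_intensity = 0))
  pairs <- sibling_attributes(tree, profiles)
  expect_identical(nrow(pairs), 1L)
  expect_equal(c(pairs$total_1, pairs$total_2), c(6, 8))
  expect_equal(c(pairs$max_1, pairs$max_2), c(3, 4))
  expect_identical(pairs$high_total_inheritor, 3)
  expect_identical(pairs$larger_sibling, 2)
})

test_that("identical daughters yield tie-flagged labels", {
  ct <- data.frame(
    frame = c(0, 1, 1), time_h = c(0, 0.25, 0.25),
    cell_id = c(1, 2, 3), parent_id = c(NA, 1, 1),
    length_um = c(4, 2, 2), new_pole_end = c("unknown", "right", "left"))
  tree <- build_lineage(ct)
  profiles <- rbind(
    data.frame(cell_id = 2, frame = 1, pixel_index = 0:2,
               parA_intensity = 5, parB_intensity = 0),
    data.frame(cell_id = 3, frame = 1, pixel_index = 0:2,
               parA_intensity = 5, parB_intensity = 0))
  pairs <- sibling_attributes(tree, profiles)
  expect_true(is.na(pairs$high_total_inheritor))
  expect_true(is.na(pairs$larger_sibling))
})

test_that("maximum-inheritor classification follows division geometry", {
  # max on the left of the plane -> left daughter
  r <- classify_max_inheritor(1.2, 2.0, 10L, 11L, 2.0, 2.5)
  expect_identical(r$inheritor, 10L)
  expect_false(r$tie)
  r2 <- classify_max_inheritor(3.1, 2.0, 10L, 11L, 2.0, 2.5)
  expect_identical(r2$inheritor, 11L)
  # on the plane: larger daughter, flagged
  r3 <- classify_max_inheritor(2.0, 2.0, 10L, 11L, 2.0, 2.5)
  expect_identical(r3$inheritor, 11L)
  expect_true(r3$tie)
})

test_that("noise-free movies attribute the maximum to the true peak side", {
  params <- sim_params(noise_sd = 0, seed = 17)
  sim <- simulate_lineage(params, 3)
  prof <- render_profiles(sim)
  cfg <- pipeline_config()
  sm <- smooth_movie(prof, sim$cells, cfg)
  tree <- build_lineage(sim$cells)
  inh <- max_inheritance_table(tree, sm$para_max, cfg)
  dv <- sim$truth$divisions
  expect_identical(nrow(inh), nrow(dv))
  for (i in seq_len(nrow(inh))) {
    d <- dv[dv$parent_id == inh$parent_id[i], ]
    # truth peak side: new-pole side iff truth max position < plane
    truth_max <- sim$truth$para_max
    tm <- truth_max$position_um[truth_max$cell_id == d$parent_id &
                                  truth_max$frame == d$frame]
    if (abs(tm - d$plane_um) <= 0.15) next  # within pixel resolution
    truth_side <- if (tm < d$plane_um) d$daughter_new_pole_side else
      d$daughter_old_pole_side
    expect_identical(inh$inheritor[i], truth_side)
  }
})

test_that("size-ratio prediction matches its closed forms", {
  one <- predict_random_inheritance(6, 4)
  expect_equal(one$expected_larger_count, 0.6)
  sym <- predict_random_inheritance(rep(2, 44), rep(2, 44))
  expect_equal(sym$expected_larger_count, 22)
  expect_equal(sym$se, sqrt(44 * 0.25))
})

test_that("per-division probabilities sum to one and rescale invariantly", {
  set.seed(30)
  big <- runif(50, 2, 3)
  small <- big * runif(50, 0.5, 1)
  pr <- predict_random_inheritance(big, small)
  pr_small <- predict_random_inheritance(small, big)
  expect_equal(pr$probabilities + pr_small$probabilities, rep(1, 50))
  scaled <- predict_random_inheritance(7 * big, 7 * small)
  expect_equal(scaled$expected_larger_count, pr$expected_larger_count)
})

test_that("uniform-random maximum placement converges to the prediction", {
  set.seed(9)
  n <- 10000
  s <- pmin(pmax(rnorm(n, 0.57, 0.03), 0.5), 0.95)
  larger <- s
  smaller <- 1 - s
  # place a maximum uniformly on [0, 1): the larger daughter inherits it
  # with probability equal to its share
  u <- runif(n)
  observed <- sum(u < larger)
  pred <- predict_random_inheritance(larger, smaller, observed)
  expect_lt(abs(pred$observed_larger_count / pred$expected_larger_count - 1),
            0.02)
})

test_that("Welch and Wilcoxon group comparisons behave at the boundaries", {
  set.seed(3)
  base <- rnorm(10, 10, 1)
  same <- compare_inheritor_groups(base, base)
  expect_equal(same$welch_statistic, 0)
  expect_equal(same$welch_p, 1)
  expect_true(is.na(same$wilcoxon_p))
  expect_match(same$note, "tied")
})

test_that("constant positive paired differences attain the exact minimal p", {
  for (n in c(6, 8)) {
    high <- seq_len(n) + 1
    low <- seq_len(n)
    ex <- wilcoxon_signed_rank_exact(high, low)
    expect_equal(ex$statistic, n * (n + 1) / 2)
    expect_equal(ex$p_greater, 2^(-n))
  }
})

test_that("a growth advantage of high inheritors is detected at n = 40", {
  set.seed(14)
  low <- rnorm(40, 0.25, 0.03)
  high <- low * 1.2 + rnorm(40, 0, 0.01)
  res <- compare_inheritor_groups(high, low)
  expect_lt(res$wilcoxon_p, 0.05)
  expect_lt(res$welch_p, 0.05)
  expect_gt(res$mean_high, res$mean_low)
})

test_that("identical groups give a Kruskal-Wallis H of zero", {
  v <- rep(c(1, 2, 3, 4, 5, 6), 3)
  g <- rep(c("a", "b", "c"), each = 6)
  res <- compare_size_distributions(v, g)
  expect_equal(res$kruskal$H, 0)
  expect_true(all(res$dunn$p_adjusted == 1))
  expect_true(all(res$letters == "A"))
})

test_that("Kruskal-Wallis H matches the hand-ranked oracle on a 3x6 fixture", {
  v <- c(2.1, 2.5, 1.9, 2.3, 2.8, 2.2,
         3.0, 3.4, 2.9, 3.6, 3.1, 3.3,
         1.2, 1.5, 1.1, 1.6, 1.4, 1.3)
  g <- rep(c("wt", "over", "del"), each = 6)
  res <- compare_size_distributions(v, g)
  expect_equal(res$kruskal$H, kruskal_H_oracle(v, g), tolerance = 1e-12)
  expect_equal(res$kruskal$H, unname(kruskal.test(v, factor(g))$statistic))
})

test_that("Dunn's test flags clearly shifted groups and letters them apart", {
  set.seed(8)
  a <- rnorm(15, 2, 0.2)
  b <- rnorm(15, 4, 0.2)
  res <- compare_size_distributions(c(a, b), rep(c("a", "b"), each = 15))
  expect_lt(res$dunn$p_adjusted, 0.05)
  expect_false(res$letters["a"] == res$letters["b"])
})

test_that("undersized groups are excluded with a warning", {
  v <- c(rnorm(6), rnorm(6) + 1, rnorm(3))
  g <- rep(c("a", "b", "tiny"), c(6, 6, 3))
  expect_warning(res <- compare_size_distributions(v, g), "excluded")
  expect_identical(res$excluded, "tiny")
})
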