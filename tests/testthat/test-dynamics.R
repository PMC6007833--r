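test_that("distance to the ParA maximum is the unsigned axial gap", {
  track <- data.frame(cell_id = 1, frame = 0:2,
                      position_um = c(1.0, 3.5, 2.0))
  pm <- data.frame(cell_id = 1, frame = 0:2, position_um = c(3.5, 3.5, 2.0))
  ds <- distance_to_para_max(track, pm)
  expect_equal(ds$distance_um, c(2.5, 0, 0))
  # frames lacking a ParA maximum are skipped
  pm$position_um[2] <- NA
  expect_equal(distance_to_para_max(track, pm)$distance_um, c(2.5, 0))
  none <- distance_to_para_max(track, pm[0, ])
  expect_identical(nrow(none), 0L)
})

test_that("a constant distance series has zero MSD at every lag", {
  msd <- msd_binned(list(rep(2, 10)), frame_interval = 0.25)
  filled <- msd[msd$n_pairs > 0, ]
  expect_true(all(filled$msd_um2 == 0))
  expect_true(all(filled$bin == "[1.5,3)"))
})

test_that("a linear distance series gives exactly v^2 dt^2", {
  v <- 0.4
  t <- (0:11) * 0.25
  msd <- msd_binned(list(v * t), frame_interval = 0.25)
  filled <- msd[msd$n_pairs > 0, ]
  expect_equal(filled$msd_um2, v^2 * filled$dt_h^2, tolerance = 1e-12)
})

test_that("series are binned by initial distance; beyond 4.5 um discarded", {
  msd <- msd_binned(list(c(0.2, 0.4, 0.3), c(2.0, 2.1, 1.9),
                         c(5.0, 4.0, 3.0)))
  expect_true(all(msd$n_pairs[msd$bin == "[0,1.5)" & msd$dt_h <= 0.5] > 0))
  expect_true(all(msd$n_pairs[msd$bin == "[1.5,3)" & msd$dt_h <= 0.5] > 0))
  # the >4.5 series contributes nowhere
  expect_identical(sum(msd$n_pairs), 2L * (2L + 1L))
})

test_that("power-law fit is the identity on exact power-law curves", {
  dt <- (1:12) * 0.25
  f1 <- fit_powerlaw(dt, 2 * 0.5 * dt^1)
  expect_equal(f1$D, 0.5, tolerance = 1e-12)
  expect_equal(f1$beta, 1, tolerance = 1e-12)
  expect_identical(f1$regime, "free")
  f2 <- fit_powerlaw(dt, 2 * 0.1 * dt^0.4)
  expect_equal(f2$D, 0.1, tolerance = 1e-12)
  expect_equal(f2$beta, 0.4, tolerance = 1e-12)
  expect_identical(f2$regime, "subdiffusive")
})

test_that("undefined fits are reported as such", {
  expect_true(is.na(fit_powerlaw(c(0.25, 0.5), c(1, 2))$beta))
  # non-positive means are excluded before fitting
  f <- fit_powerlaw(c(0.25, 0.5, 0.75, 1), c(0, 1, 2, 3))
  expect_identical(f$n_lags, 3L)
})

test_that("ballistic distance series fit with beta = 2 exactly", {
  tracks <- simulate_tracks("ballistic", 5, 20, 0.25, speed = 0.6)
  series <- lapply(seq_len(nrow(tracks)), function(i) tracks[i, ] + 0.1)
  msd <- msd_binned(series, frame_interval = 0.25)
  fit <- fit_powerlaw(msd$dt_h, msd$msd_um2)
  expect_equal(fit$beta, 2, tolerance = 1e-6)
  expect_identical(fit$regime, "active")
})

test_that("Brownian and fractional ensembles recover their MSD exponents", {
  # free diffusion: beta near 1
  tb <- simulate_tracks("brownian", 200, 30, 0.25, step_scale = 0.1,
                        seed = 2)
  sb <- lapply(seq_len(nrow(tb)), function(i) tb[i, ] + 1)
  msd_b <- msd_binned(sb, frame_interval = 0.25)
  fb <- fit_powerlaw_bins(msd_b)
  fb <- fb[fb$n_lags > 0 & !is.na(fb$beta), ]
  expect_lt(abs(fb$beta - 1), 3 * fb$se_beta + 0.05)
  # sub-diffusion: beta near 2H
  h <- 0.2
  ts <- simulate_tracks("subdiffusive", 200, 30, 0.25, step_scale = 0.1,
                        hurst = h, seed = 3)
  ss <- lapply(seq_len(nrow(ts)), function(i) ts[i, ] + 1)
  fs <- fit_powerlaw_bins(msd_binned(ss, frame_interval = 0.25))
  fs <- fs[fs$n_lags > 0 & !is.na(fs$beta), ]
  expect_lt(abs(fs$beta - 2 * h), 3 * fs$se_beta + 0.05)
})

test_that("fGn bin means lie on the fractional MSD curve", {
  h <- 0.2
  sc <- 0.1
  tr <- simulate_tracks("subdiffusive", 300, 30, 0.25, step_scale = sc,
                        hurst = h, seed = 5)
  series <- lapply(seq_len(nrow(tr)), function(i) tr[i, ] + 1)
  msd <- msd_binned(series, frame_interval = 0.25)
  msd <- msd[msd$n_pairs > 0 & msd$dt_h <= 10 * 0.25, ]
  # stationary fGn increments: E[dx^2] at lag k is sc^2 k^{2H}
  expected <- sc^2 * (msd$dt_h / 0.25)^(2 * h)
  inside <- expected >= msd$ci_low & expected <= msd$ci_high
  expect_gte(mean(inside), 0.7)
})

test_that("velocity classification follows the 0.15 um/h threshold", {
  t <- (0:10) * 0.25
  expect_identical(classify_velocity(t, 2 - 0.3 * t)$class, "toward")
  expect_identical(classify_velocity(t, 2 + 0.05 * t)$class, "with")
  expect_identical(classify_velocity(t, 2 + 0.20 * t)$class, "away")
  expect_true(is.na(classify_velocity(t[1:2], c(1, 2))$class))
})

test_that("velocity classification is antisymmetric in the trend", {
  set.seed(12)
  t <- (0:19) * 0.25
  for (rep in 1:10) {
    d <- 2 + cumsum(rnorm(20, 0, 0.1))
    a <- classify_velocity(t, d)
    b <- classify_velocity(t, 4 - (d - 2))
    expect_equal(a$slope, -b$slope)
    flip <- c(toward = "away", with = "with", away = "toward")
    expect_identical(unname(flip[a$class]), b$class)
  }
})

test_that("directionality summary counts and combines classes", {
  s <- summarize_directionality(c("toward", "away"))
  expect_equal(s$fraction, c(0.5, 0, 0.5))
  s2 <- summarize_directionality(rep("with", 4))
  expect_equal(attr(s2, "toward_or_with"), 1)
})

test_that("symmetric motion regimes split toward-or-with and away evenly", {
  # equal numbers of inward and outward drifting series
  t <- (0:19) * 0.25
  n <- 60
  set.seed(21)
  classes <- character(2 * n)
  for (i in seq_len(n)) {
    drift <- 0.4
    classes[2 * i - 1] <- classify_velocity(
      t, 3 - drift * t + rnorm(20, 0, 0.05))$class
    classes[2 * i] <- classify_velocity(
      t, 1 + drift * t + rnorm(20, 0, 0.05))$class
  }
  s <- summarize_directionality(classes)
  p <- attr(s, "toward_or_with")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / (2 * n)))
})
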