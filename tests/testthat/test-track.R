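foci_df <- function(...) {
  m <- rbind(...)
  data.frame(cell_id = m[, 1], frame = m[, 2], position_px = m[, 3],
             position_um = m[, 3] * 0.1, intensity = 1,
             validation_count = 20L)
}

one_cell_table <- function(frames, cell_id = 1, length_um = 5) {
  data.frame(frame = frames, time_h = frames * 0.25, cell_id = cell_id,
             parent_id = NA_integer_, length_um = length_um,
             new_pole_end = "unknown")
}

test_that("foci within the link radius join one track, beyond it two", {
  ct <- one_cell_table(0:1)
  tree <- build_lineage(ct)
  near <- link_foci(foci_df(c(1, 0, 10), c(1, 1, 12)), ct, tree,
                    pipeline_config())
  expect_identical(length(unique(near$track_id)), 1L)
  far <- link_foci(foci_df(c(1, 0, 10), c(1, 1, 17)), ct, tree,
                   pipeline_config())
  expect_identical(length(unique(far$track_id)), 2L)
})

test_that("link conflicts resolve to the nearest focus; the loser starts anew", {
  # two foci at frame 0, one at frame 1 within reach of both
  ct <- one_cell_table(0:1)
  tree <- build_lineage(ct)
  tr <- link_foci(foci_df(c(1, 0, 10), c(1, 0, 14), c(1, 1, 13)), ct, tree,
                  pipeline_config())
  expect_identical(length(unique(tr$track_id)), 2L)
  winner <- tr$track_id[tr$frame == 1]
  expect_identical(winner, tr$track_id[tr$frame == 0 & tr$position_px == 14])
})

test_that("a lone focus per frame forms a single track under a loose radius", {
  frames <- 0:9
  set.seed(3)
  pos <- cumsum(c(25, sample(-20:20, 9, TRUE)))
  pos <- pmax(pos, 0)
  ct <- one_cell_table(frames)
  tree <- build_lineage(ct)
  m <- do.call(rbind, lapply(seq_along(frames),
                             function(i) c(1, frames[i], pos[i])))
  tr <- link_foci(foci_df(m), ct, tree, pipeline_config(link_max_px = 1e6))
  expect_identical(length(unique(tr$track_id)), 1L)
})

test_that("every validated focus lands in exactly one track", {
  s <- make_default_movie()
  sm <- smooth_movie(s$profiles, s$sim$cells, s$config)
  foci <- detect_foci(sm$smoothed, s$sim$cells, s$config)
  tree <- build_lineage(s$sim$cells)
  tracks <- link_foci(foci, s$sim$cells, tree, s$config)
  expect_identical(nrow(tracks), nrow(foci))
  expect_false(any(is.na(tracks$track_id)))
  # at most one focus per frame per track
  expect_false(any(duplicated(tracks[, c("track_id", "frame")])))
})

test_that("links agree with ground-truth focus identities on the default movie", {
  s <- make_default_movie()
  sm <- smooth_movie(s$profiles, s$sim$cells, s$config)
  foci <- detect_foci(sm$smoothed, s$sim$cells, s$config)
  tree <- build_lineage(s$sim$cells)
  tracks <- link_foci(foci, s$sim$cells, tree, s$config)
  tf <- s$sim$truth$foci
  good <- 0L
  bad <- 0L
  for (tid in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == tid, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2L) next
    ids <- mapply(function(c, f, p) truth_focus_id(tf, c, f, p),
                  tr$cell_id, tr$frame, tr$position_um)
    for (k in 2:nrow(tr)) {
      if (is.na(ids[k]) || is.na(ids[k - 1])) next
      if (ids[k] == ids[k - 1]) good <- good + 1L else bad <- bad + 1L
    }
  }
  expect_gte(good / (good + bad), 0.95)
})

test_that("tracks follow foci across divisions via plane remapping", {
  # parent (frames 0-1, length 4, left-referenced) divides into a left
  # daughter of 2.2 (new pole right) and right daughter of 1.8 (new pole
  # left); a focus at lab 1.0 um maps to 1.2 um from the left daughter's
  # new pole
  ct <- data.frame(
    frame = c(0, 1, 2, 2), time_h = c(0, 0.25, 0.5, 0.5),
    cell_id = c(1, 1, 2, 3), parent_id = c(NA, NA, 1, 1),
    length_um = c(3.8, 4.0, 2.2, 1.8),
    new_pole_end = c("unknown", "unknown", "right", "left"))
  tree <- build_lineage(ct)
  foci <- foci_df(c(1, 0, 10), c(1, 1, 10), c(2, 2, 12))
  tr <- link_foci(foci, ct, tree, pipeline_config())
  expect_identical(length(unique(tr$track_id)), 1L)
})

test_that("split proposals fire on one-ends-two-begin patterns only", {
  ct <- one_cell_table(0:3)
  tree <- build_lineage(ct)
  foci <- foci_df(c(1, 0, 30), c(1, 1, 30),
                  c(1, 2, 23), c(1, 2, 37),
                  c(1, 3, 22), c(1, 3, 38))
  tracks <- link_foci(foci, ct, tree, pipeline_config())
  sp <- assign_splits(tracks, pipeline_config())
  expect_identical(nrow(sp), 1L)
  parent <- tracks$track_id[tracks$frame == 0]
  kids <- unique(tracks$track_id[tracks$frame == 3])
  expect_identical(sp$parent_track_id, parent)
  expect_setequal(c(sp$child_track_id_1, sp$child_track_id_2), kids)
})

test_that("three candidate children suppress the proposal with a warning", {
  ct <- one_cell_table(0:1)
  tree <- build_lineage(ct)
  foci <- foci_df(c(1, 0, 30),
                  c(1, 1, 24), c(1, 1, 31), c(1, 1, 38))
  tracks <- link_foci(foci, ct, tree,
                      pipeline_config(link_max_px = 0))
  expect_warning(sp <- assign_splits(tracks, pipeline_config()),
                 "candidate children")
  expect_identical(nrow(sp), 0L)
  expect_length(attr(sp, "flagged"), 1L)
})

test_that("overrides apply in order and enforce track invariants", {
  ct <- one_cell_table(0:3)
  tree <- build_lineage(ct)
  foci <- foci_df(c(1, 0, 10), c(1, 1, 12),
                  c(1, 2, 30), c(1, 3, 32))
  tracks <- link_foci(foci, ct, tree, pipeline_config())
  splits <- assign_splits(tracks, pipeline_config())
  expect_identical(length(unique(tracks$track_id)), 2L)

  # empty file is the identity
  f <- withr::local_tempfile(lines = character(0))
  out <- apply_overrides(tracks, splits, f)
  expect_identical(out$tracks, tracks)

  # merging disjoint tracks yields one contiguous track
  ids <- sort(unique(tracks$track_id))
  f2 <- withr::local_tempfile(lines = sprintf("merge %d %d", ids[1], ids[2]))
  merged <- apply_overrides(tracks, splits, f2)
  expect_identical(length(unique(merged$tracks$track_id)), 1L)

  # merge that would duplicate a frame is rejected
  clash <- foci_df(c(1, 0, 10), c(1, 0, 40))
  tr2 <- link_foci(clash, one_cell_table(0), tree, pipeline_config())
  f3 <- withr::local_tempfile(lines = "merge 1 2")
  expect_error(apply_overrides(tr2, splits, f3), "same frame")

  # dangling ids are a hard error
  f4 <- withr::local_tempfile(lines = "merge 1 99")
  expect_error(apply_overrides(tracks, splits, f4), "unknown track id")
})
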