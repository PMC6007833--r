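#' Distance series of every track to the ParA maximum
#'
#' @param tracks track table from [link_foci()].
#' @param para_max per-frame maxima from [smooth_movie()].
#' @param config a [pipeline_config()].
#' @return list: `table` (long data.frame `track_id`, `frame`, `time_h`,
#'   `distance_um`), `series` (named list of distance vectors, one per
#'   track, frame-ordered).
#' @export
track_distance_series <- function(tracks, para_max,
                                  config = pipeline_config()) {
  out_tab <- list()
  series <- list()
  for (tid in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == tid, ]
    ds <- distance_to_para_max(tr, para_max)
    if (nrow(ds) == 0L) next
    out_tab[[length(out_tab) + 1L]] <- data.frame(
      track_id = tid, frame = ds$frame,
      time_h = ds$frame * config$frame_interval_h,
      distance_um = ds$distance_um)
    series[[as.character(tid)]] <- ds$distance_um
  }
  tab <- if (length(out_tab)) do.call(rbind, out_tab) else
    data.frame(track_id = integer(0), frame = integer(0),
               time_h = numeric(0), distance_um = numeric(0))
  rownames(tab) <- NULL
  list(table = tab, series = series)
}

#' Run the full analysis pipeline on a movie
#'
#' Smooths both channels, locates per-frame ParA maxima, detects and
#' validates ParB foci, links them into tracks with split proposals (and
#' optional manual overrides), computes binned MSD curves with per-bin
#' power-law fits, classifies per-track velocities, and quantifies ParA
#' inheritance between siblings, alongside per-cell lineage statistics.
#'
#' @param cell_table cell table (see [read_cell_table()] for the schema).
#' @param profiles profile table (see [read_profile_table()]).
#' @param config a [pipeline_config()].
#' @param override_file optional curation override file for
#'   [apply_overrides()].
#' @return list of class `parab_results`: `tree`, `smoothed`, `para_max`,
#'   `foci`, `tracks`, `splits`, `distances`, `msd`, `fits`, `velocity`,
#'   `directionality`, `sibling_pairs`, `inheritance`,
#'   `inheritance_prediction`, `cell_stats`, `config`.
#' @export
run_pipeline <- function(cell_table, profiles, config = pipeline_config(),
                         override_file = NULL) {
  tree <- build_lineage(cell_table)
  sm <- smooth_movie(profiles, cell_table, config)
  foci <- detect_foci(sm$smoothed, cell_table, config)
  tracks <- link_foci(foci, cell_table, tree, config)
  splits <- assign_splits(tracks, config)
  cur <- apply_overrides(tracks, splits, override_file)
  tracks <- cur$tracks
  splits <- cur$splits

  dist <- track_distance_series(tracks, sm$para_max, config)
  msd <- msd_binned(dist$series, config$msd_bin_edges_um,
                    config$frame_interval_h)
  fits <- fit_powerlaw_bins(msd, config$msd_max_lag_frac)

  vel_rows <- lapply(names(dist$series), function(tid) {
    sub <- dist$table[dist$table$track_id == as.integer(tid), ]
    v <- classify_velocity(sub$time_h, sub$distance_um,
                           config$velocity_threshold_um_h)
    data.frame(track_id = as.integer(tid), slope_um_per_h = v$slope,
               class = v$class)
  })
  velocity <- if (length(vel_rows)) do.call(rbind, vel_rows) else
    data.frame(track_id = integer(0), slope_um_per_h = numeric(0),
               class = character(0))
  directionality <- if (any(!is.na(velocity$class))) {
    summarize_directionality(velocity$class)
  } else NULL

  pairs <- sibling_attributes(tree, profiles)
  inheritance <- max_inheritance_table(tree, sm$para_max, config)
  prediction <- if (nrow(inheritance) > 0L) {
    # larger/smaller birth lengths per division
    len_l <- vapply(seq_len(nrow(inheritance)), function(i) {
      ct <- tree$cells[tree$cells$cell_id == inheritance$left_daughter[i], ]
      ct$length_um[which.min(ct$frame)]
    }, 0)
    len_r <- vapply(seq_len(nrow(inheritance)), function(i) {
      ct <- tree$cells[tree$cells$cell_id == inheritance$right_daughter[i], ]
      ct$length_um[which.min(ct$frame)]
    }, 0)
    predict_random_inheritance(pmax(len_l, len_r), pmin(len_l, len_r),
                               sum(inheritance$larger_inherits))
  } else NULL

  structure(
    list(tree = tree, smoothed = sm$smoothed, para_max = sm$para_max,
         foci = foci, tracks = tracks, splits = splits,
         distances = dist$table, msd = msd, fits = fits,
         velocity = velocity, directionality = directionality,
         sibling_pairs = pairs, inheritance = inheritance,
         inheritance_prediction = prediction,
         cell_stats = cell_statistics(tree, config$minicell_max_um),
         config = config),
    class = "parab_results"
  )
}

#' Write the pipeline result bundle to disk
#'
#' CSV for the tabular stages, JSON for fits and inheritance prediction.
#'
#' @param results a `parab_results` bundle.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$foci, "foci.csv")
  wr(results$tracks, "tracks.csv")
  wr(results$distances, "distances.csv")
  wr(as.data.frame(results$msd), "msd.csv")
  wr(results$fits, "msd_fits.csv")
  wr(results$velocity, "velocity.csv")
  if (nrow(results$inheritance) > 0L) wr(results$inheritance,
                                         "inheritance.csv")
  wr(results$cell_stats, "cell_stats.csv")
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(
      fits = results$fits,
      directionality = if (!is.null(results$directionality)) list(
        counts = results$directionality,
        toward_or_with = attr(results$directionality, "toward_or_with")
      ) else NULL,
      inheritance_prediction =
        results$inheritance_prediction[c("n_divisions",
                                         "expected_larger_count", "se",
                                         "observed_larger_count")],
      config = unclass(results$config)
    ),
    p, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Render a kymograph of one cell's ParA heatmap with ParB tracks
#'
#' Space-time rendering of a single cell: grayscale lifetime-normalised
#' ParA intensity (black = minimum, white = maximum) with the cell's ParB
#' focus tracks overlaid as lines, the new pole at the bottom of the
#' panel.
#'
#' @param cell_id cell to render.
#' @param smoothed smoothed profile table from [smooth_movie()].
#' @param cell_table cell table.
#' @param tracks track table (optional; `NULL` renders heatmap only).
#' @param config a [pipeline_config()].
#' @param file output PNG path (`NULL` draws on the active device).
#' @return invisibly, the heatmap matrix (frames x pixels, pole-relative).
#' @export
render_kymograph <- function(cell_id, smoothed, cell_table, tracks = NULL,
                             config = pipeline_config(), file = NULL) {
  sub <- smoothed[smoothed$cell_id == cell_id, ]
  if (nrow(sub) == 0L) stop("no profiles for cell ", cell_id, call. = FALSE)
  npe <- cell_table$new_pole_end[match(cell_id, cell_table$cell_id)]
  frames <- sort(unique(sub$frame))
  n_px_max <- max(tapply(sub$pixel_index, sub$frame, length))
  mat <- matrix(NA_real_, nrow = length(frames), ncol = n_px_max)
  for (i in seq_along(frames)) {
    v <- sub[sub$frame == frames[i], ]
    v <- v[order(v$pixel_index), "parA_smooth"]
    if (identical(npe, "right")) v <- rev(v)  # new pole to index 1 (bottom)
    mat[i, seq_along(v)] <- v
  }
  hm <- normalize_para_heatmap(split(mat, row(mat)))
  mat_n <- do.call(rbind, hm$frames)

  draw <- function() {
    graphics::image(
      x = frames * config$frame_interval_h,
      y = (seq_len(n_px_max) - 1L) * config$pixel_size_um,
      z = mat_n, col = grDevices::gray.colors(256, start = 0, end = 1),
      xlab = "time (h)", ylab = "distance from new pole (um)",
      main = paste("cell", cell_id), useRaster = FALSE
    )
    if (!is.null(tracks)) {
      tr <- tracks[tracks$cell_id == cell_id, ]
      for (tid in unique(tr$track_id)) {
        one <- tr[tr$track_id == tid, ]
        one <- one[order(one$frame), ]
        graphics::lines(one$frame * config$frame_interval_h,
                        one$position_um, lwd = 2, col = "grey40")
        graphics::points(one$frame * config$frame_interval_h,
                         one$position_um, pch = 16, cex = 0.5)
      }
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(mat_n)
}
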