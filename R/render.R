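#' Render axial fluorescence profiles from simulated ground truth
#'
#' Converts a simulated lineage into the 1-D per-cell, per-frame profiles
#' the analysis consumes. The ParB channel is a background plus one
#' Gaussian spot (sd `spot_sigma`) per true focus; the ParA channel is a
#' baseline plus a Gaussian bump (sd `parA_peak_width`) at the true maximum
#' position; both carry i.i.d. Gaussian pixel noise (sd `noise_sd`). The
#' pixel grid has points at `0, pixel_size, 2 * pixel_size, ...` spanning
#' `[0, L]` in the lab frame; cell-frame positions (measured from the new
#' pole) are mirrored into the lab frame for right-oriented cells.
#'
#' Cells shorter than 3 pixels are dropped (with a warning), mirroring the
#' minimum trace length the analysis requires.
#'
#' @param sim a `sim_lineage` from [simulate_lineage()], or a list with
#'   elements `cells`, `truth`, `params` of the same shape.
#' @return a data.frame with columns `cell_id`, `frame`, `pixel_index`
#'   (0-based), `parA_intensity`, `parB_intensity`.
#' @export
render_profiles <- function(sim) {
  stopifnot(is.list(sim), !is.null(sim$cells), !is.null(sim$truth),
            !is.null(sim$params))
  params <- sim$params
  cells <- sim$cells
  if (nrow(cells) == 0L) stop("no frames to render", call. = FALSE)
  set.seed(spawn_seed(params$seed, "render"))
  px <- params$pixel_size

  truth_foci <- sim$truth$foci
  truth_para <- sim$truth$para_max
  out <- vector("list", nrow(cells))
  dropped <- 0L
  for (r in seq_len(nrow(cells))) {
    L <- cells$length_um[r]
    n_px <- floor(L / px + 1e-9) + 1L
    if (n_px < 3L) {
      dropped <- dropped + 1L
      next
    }
    cid <- cells$cell_id[r]
    fr <- cells$frame[r]
    # lab-frame pixel positions; mirror cell-frame (new-pole-origin)
    # positions for right-oriented cells
    x_lab <- (seq_len(n_px) - 1L) * px
    flip <- identical(cells$new_pole_end[r], "right")
    to_lab <- function(x_cell) if (flip) L - x_cell else x_cell

    fpos <- truth_foci$position_um[truth_foci$cell_id == cid &
                                     truth_foci$frame == fr]
    parB <- rep(params$parA_baseline, n_px)
    for (xf in fpos) {
      parB <- parB + params$spot_amplitude *
        exp(-(x_lab - to_lab(xf))^2 / (2 * params$spot_sigma^2))
    }
    apos <- truth_para$position_um[truth_para$cell_id == cid &
                                     truth_para$frame == fr]
    parA <- rep(params$parA_baseline, n_px)
    if (length(apos) == 1L) {
      parA <- parA + params$parA_amplitude *
        exp(-(x_lab - to_lab(apos))^2 / (2 * params$parA_peak_width^2))
    }
    if (params$noise_sd > 0) {
      parA <- parA + stats::rnorm(n_px, 0, params$noise_sd)
      parB <- parB + stats::rnorm(n_px, 0, params$noise_sd)
    }
    out[[r]] <- data.frame(
      cell_id = cid, frame = fr, pixel_index = seq_len(n_px) - 1L,
      parA_intensity = pmax(parA, 0), parB_intensity = pmax(parB, 0)
    )
  }
  if (dropped > 0L) {
    warning(sprintf("%d cell frame(s) shorter than 3 pixels dropped", dropped))
  }
  kept <- out[!vapply(out, is.null, TRUE)]
  if (length(kept) == 0L) {
    stop("all cell frames were shorter than 3 pixels; nothing rendered",
         call. = FALSE)
  }
  res <- do.call(rbind, kept)
  rownames(res) <- NULL
  res
}

#' Write a simulated data set to disk
#'
#' Emits the cell table and long-format profile table as CSV and the ground
#' truth as JSON, the on-disk interchange format of the pipeline.
#'
#' @param sim a `sim_lineage`.
#' @param profiles the profile table from [render_profiles()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, profiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_cells <- file.path(dir, "cells.csv")
  p_prof <- file.path(dir, "profiles.csv")
  p_truth <- file.path(dir, "ground_truth.json")
  utils::write.csv(sim$cells, p_cells, row.names = FALSE)
  utils::write.csv(profiles, p_prof, row.names = FALSE)
  jsonlite::write_json(
    list(foci = sim$truth$foci, para_max = sim$truth$para_max,
         divisions = sim$truth$divisions, splits = sim$truth$splits,
         params = unclass(sim$params)),
    p_truth, digits = NA, auto_unbox = TRUE
  )
  invisible(c(cells = p_cells, profiles = p_prof, truth = p_truth))
}

#' Read a cell table written by [write_simulation()]
#' @param path CSV path.
#' @return the cell table data.frame.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_h", "cell_id", "parent_id", "length_um",
            "new_pole_end")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cell table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a profile table written by [write_simulation()]
#' @param path CSV path.
#' @return the profile table data.frame.
#' @export
read_profile_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "pixel_index", "parA_intensity",
            "parB_intensity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("profile table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}
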