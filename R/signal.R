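#' Gaussian smoothing of an axial fluorescence profile
#'
#' Discrete Gaussian convolution along the cell axis with reflective
#' boundary handling, so pole-proximal signal is not dimmed by the edge.
#' The kernel is a normalised sampled Gaussian truncated at 4 sigma.
#'
#' @param intensities numeric vector of pixel intensities (length >= 3).
#' @param sigma_px kernel standard deviation in pixels.
#' @return smoothed vector of the same length.
#' @export
smooth_profile <- function(intensities, sigma_px = 2) {
  stopifnot(is.numeric(intensities), length(intensities) >= 3L)
  assert_scalar_num(sigma_px, "sigma_px", lower = 0, lower_open = TRUE)
  half <- max(1L, ceiling(4 * sigma_px))
  kern <- stats::dnorm(-half:half, sd = sigma_px)
  kern <- kern / sum(kern)
  n <- length(intensities)
  # reflective padding: mirror without repeating the edge pixel
  idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  padded <- intensities[idx]
  out <- stats::convolve(padded, rev(kern), type = "filter")
  as.numeric(out)
}

#' Lifetime-normalised ParA heatmap for one cell
#'
#' Divides every smoothed per-frame ParA profile of a cell by the single
#' maximum intensity over the cell's whole lifetime (birth to division), so
#' values lie in `[0, 1]` with exactly one lifetime-wide 1 (absent ties).
#'
#' @param profiles named list (one element per frame, in frame order) of
#'   smoothed ParA intensity vectors.
#' @return list of class `para_heatmap`: `frames` (the normalised
#'   profiles), `lifetime_max`, `all_zero` flag.
#' @export
normalize_para_heatmap <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  m <- max(c(unlist(profiles), 0), na.rm = TRUE)
  if (m <= 0) {
    warning("all-zero ParA signal; heatmap left at zero")
    return(structure(list(frames = profiles, lifetime_max = 0,
                          all_zero = TRUE), class = "para_heatmap"))
  }
  structure(list(frames = lapply(profiles, function(p) p / m),
                 lifetime_max = m, all_zero = FALSE),
            class = "para_heatmap")
}

#' Position of the ParA maximum along the cell axis
#'
#' Argmax of a smoothed ParA profile, converted to um from the new pole.
#' Ties are broken toward the new pole. A flat profile has no maximum and
#' returns `NA` (the frame is then excluded from distance-based analyses).
#'
#' @param intensities smoothed ParA profile (pixel values, lab order).
#' @param pixel_size um per pixel.
#' @param new_pole_end `"left"`, `"right"`, or `"unknown"` — the lab end
#'   holding the new pole; `"unknown"` falls back to the left pole as the
#'   reference.
#' @return position in um from the reference pole (`NA` if flat).
#' @export
para_maximum <- function(intensities, pixel_size, new_pole_end = "left") {
  n <- length(intensities)
  stopifnot(n >= 1L)
  if (diff(range(intensities)) == 0) return(NA_real_)
  # pole-relative pixel distances; tie-break toward the new pole =
  # smallest pole-relative distance among maximal pixels
  d_px <- if (identical(new_pole_end, "right")) (n - 1L):0 else 0:(n - 1L)
  mx <- which(intensities == max(intensities))
  best <- mx[which.min(d_px[mx])]
  d_px[best] * pixel_size
}

#' Smooth all profiles of a movie and locate per-frame ParA maxima
#'
#' Convenience wrapper applying [smooth_profile()] to both channels of a
#' long-format profile table and [para_maximum()] to the smoothed ParA
#' channel of every cell frame.
#'
#' @param profiles profile table (`cell_id`, `frame`, `pixel_index`,
#'   `parA_intensity`, `parB_intensity`).
#' @param cell_table cell table supplying `new_pole_end` per cell.
#' @param config a [pipeline_config()].
#' @return list: `smoothed` (profile table with `parA_smooth`,
#'   `parB_smooth` columns), `para_max` (data.frame `cell_id`, `frame`,
#'   `position_um`, `position_px`).
#' @export
smooth_movie <- function(profiles, cell_table, config = pipeline_config()) {
  profiles <- profiles[order(profiles$cell_id, profiles$frame,
                             profiles$pixel_index), ]
  rownames(profiles) <- NULL
  key <- interaction(profiles$cell_id, profiles$frame, drop = TRUE)
  parts <- split(seq_len(nrow(profiles)), key)
  profiles$parA_smooth <- NA_real_
  profiles$parB_smooth <- NA_real_
  pm_rows <- vector("list", length(parts))
  i <- 0L
  for (rows in parts) {
    i <- i + 1L
    a <- smooth_profile(profiles$parA_intensity[rows],
                        config$smoothing_sigma_px)
    b <- smooth_profile(profiles$parB_intensity[rows],
                        config$smoothing_sigma_px)
    profiles$parA_smooth[rows] <- a
    profiles$parB_smooth[rows] <- b
    npe <- cell_table$new_pole_end[
      match(profiles$cell_id[rows[1L]], cell_table$cell_id)]
    pos <- para_maximum(a, config$pixel_size_um, npe)
    pm_rows[[i]] <- data.frame(
      cell_id = profiles$cell_id[rows[1L]],
      frame = profiles$frame[rows[1L]],
      position_um = pos,
      position_px = if (is.na(pos)) NA_integer_ else
        as.integer(round(pos / config$pixel_size_um))
    )
  }
  para_max <- do.call(rbind, pm_rows)
  rownames(para_max) <- NULL
  list(smoothed = profiles, para_max = para_max)
}
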