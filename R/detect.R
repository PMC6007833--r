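#' Detect candidate ParB peaks on a smoothed profile
#'
#' Local maxima (downward zero-crossings of the first derivative), kept if
#' they rise above `threshold_rel` of the baseline-subtracted trace maximum
#' and, within any window of `min_separation_px` pixels, only the highest
#' peak survives (greedy highest-first suppression). Plateau maxima are
#' reported at their first (lowest-index) pixel.
#'
#' @param intensities smoothed trace (length >= 3).
#' @param min_separation_px peaks closer than or equal to this many pixels
#'   to a stronger peak are suppressed.
#' @param threshold_rel height threshold as a fraction of
#'   `max(trace) - min(trace)` above `min(trace)`; scale- and offset-free.
#' @return integer vector of 0-based peak pixel indices (possibly empty),
#'   ordered by position.
#' @export
detect_peaks <- function(intensities, min_separation_px = 5,
                         threshold_rel = 0.3) {
  n <- length(intensities)
  stopifnot(n >= 3L)
  lo <- min(intensities)
  hi <- max(intensities)
  if (hi == lo) return(integer(0))
  thr <- lo + threshold_rel * (hi - lo)
  d <- diff(intensities)
  # downward zero-crossing of the first derivative: rising (or flat after
  # rising) then falling
  cand <- integer(0)
  rising <- FALSE
  plateau_start <- NA_integer_
  for (i in seq_len(n - 1L)) {
    if (d[i] > 0) {
      rising <- TRUE
      plateau_start <- NA_integer_
    } else if (d[i] < 0) {
      if (rising) {
        cand <- c(cand, if (is.na(plateau_start)) i else plateau_start)
      }
      rising <- FALSE
      plateau_start <- NA_integer_
    } else if (rising && is.na(plateau_start)) {
      plateau_start <- i
    }
  }
  cand <- cand[intensities[cand] >= thr]
  if (length(cand) <= 1L) return(as.integer(cand - 1L))
  # greedy highest-first suppression of the separation constraint
  ord <- cand[order(-intensities[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) > min_separation_px)) {
      kept <- c(kept, p)
    }
  }
  as.integer(sort(kept) - 1L)
}

#' Validate candidate peaks by noise perturbation
#'
#' The false-positive filter: `n_trials` times, i.i.d. Gaussian noise with
#' sd equal to `noise_sigma_factor` times the sd of the smoothed trace is
#' added, the trace is re-smoothed, and peaks are re-detected. A candidate
#' is retained if a re-detected peak falls within `match_radius_px` of it
#' in at least `retain_min` trials.
#'
#' @param intensities smoothed trace the candidates came from.
#' @param candidates 0-based candidate pixel indices from [detect_peaks()].
#' @param config a [pipeline_config()] (fields `noise_trials`,
#'   `noise_retain_min`, `noise_sigma_factor`, `resmooth_sigma_px`,
#'   `match_radius_px`, `peak_min_separation_px`, `peak_threshold_rel`).
#' @param seed integer seed for the perturbation draws.
#' @return data.frame `position_px` (0-based), `validation_count`,
#'   `retained`; one row per candidate.
#' @export
validate_peaks <- function(intensities, candidates,
                           config = pipeline_config(), seed = 0L) {
  if (length(candidates) == 0L) {
    return(data.frame(position_px = integer(0),
                      validation_count = integer(0),
                      retained = logical(0)))
  }
  sdev <- stats::sd(intensities)
  counts <- integer(length(candidates))
  if (sdev == 0) {
    # zero-variance trace: no perturbation possible, candidates stand
    warning("zero-variance profile; peaks retained without validation")
    counts[] <- config$noise_trials
  } else {
    set.seed(seed)
    for (t in seq_len(config$noise_trials)) {
      noisy <- intensities +
        stats::rnorm(length(intensities), 0, config$noise_sigma_factor * sdev)
      resm <- smooth_profile(noisy, config$resmooth_sigma_px)
      found <- detect_peaks(resm, config$peak_min_separation_px,
                            config$peak_threshold_rel)
      if (length(found)) {
        hit <- vapply(candidates, function(p) {
          any(abs(found - p) <= config$match_radius_px)
        }, TRUE)
        counts <- counts + hit
      }
    }
  }
  data.frame(position_px = as.integer(candidates),
             validation_count = counts,
             retained = counts >= config$noise_retain_min)
}

#' Detect and validate ParB foci over a whole movie
#'
#' Runs [detect_peaks()] and [validate_peaks()] on the smoothed ParB trace
#' of every cell frame, reporting pole-relative positions.
#'
#' @param smoothed smoothed profile table from [smooth_movie()].
#' @param cell_table cell table (`new_pole_end` per cell).
#' @param config a [pipeline_config()].
#' @param seed integer base seed; each cell frame gets a derived stream.
#' @return data.frame of validated foci: `cell_id`, `frame`, `position_px`
#'   (pole-relative pixels), `position_um`, `intensity`,
#'   `validation_count`.
#' @export
detect_foci <- function(smoothed, cell_table, config = pipeline_config(),
                        seed = config$seed) {
  key <- interaction(smoothed$cell_id, smoothed$frame, drop = TRUE)
  parts <- split(seq_len(nrow(smoothed)), key)
  out <- list()
  for (rows in parts) {
    rows <- rows[order(smoothed$pixel_index[rows])]
    trace <- smoothed$parB_smooth[rows]
    cid <- smoothed$cell_id[rows[1L]]
    fr <- smoothed$frame[rows[1L]]
    cand <- detect_peaks(trace, config$peak_min_separation_px,
                         config$peak_threshold_rel)
    if (!length(cand)) next
    val <- validate_peaks(trace, cand, config,
                          seed = spawn_seed(seed,
                                            paste0("detect/", cid, "/", fr)))
    val <- val[val$retained, ]
    if (!nrow(val)) next
    n <- length(trace)
    npe <- cell_table$new_pole_end[match(cid, cell_table$cell_id)]
    # pole-relative pixel distance (new pole when known, else left pole)
    pr_px <- if (identical(npe, "right")) (n - 1L) - val$position_px
             else val$position_px
    out[[length(out) + 1L]] <- data.frame(
      cell_id = cid, frame = fr,
      position_px = pr_px,
      position_um = pr_px * config$pixel_size_um,
      intensity = trace[val$position_px + 1L],
      validation_count = val$validation_count
    )
  }
  if (!length(out)) {
    return(data.frame(cell_id = integer(0), frame = integer(0),
                      position_px = integer(0), position_um = numeric(0),
                      intensity = numeric(0), validation_count = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$cell_id, res$frame, res$position_px), ]
  rownames(res) <- NULL
  res
}
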