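#' Simulate a ground-truthed cell lineage
#'
#' Grows exponentially elongating rod cells that divide asymmetrically at a
#' fixed division length, with polarity bookkeeping (each daughter's new
#' pole is the end created at the division plane), a ParA maximum placed
#' near the new pole that relocates to the division plane just before
#' division, and ParB foci that split once per cell cycle: one child focus
#' stays in the sub-diffusive near-ParA regime, the other segregates toward
#' the old pole, switching to directed motion once it is farther than
#' `regime_switch_distance` from the ParA maximum.
#'
#' Positions in the returned ground truth are measured in um from the
#' cell's new pole (from the left pole for the root, whose new pole is
#' unknown). The cell table reports the lab-frame end (`"left"`/`"right"`)
#' at which each cell's new pole sits, `"unknown"` for the root.
#'
#' @param params a [sim_params()] object.
#' @param n_generations number of generations to simulate (>= 1); the
#'   lineage contains `2^n_generations - 1` cells.
#' @return a list of class `sim_lineage` with elements
#'   \describe{
#'     \item{cells}{data.frame: `frame`, `time_h`, `cell_id`, `parent_id`,
#'       `length_um`, `new_pole_end`.}
#'     \item{truth}{list with data.frames `foci` (`frame`, `cell_id`,
#'       `focus_id`, `position_um`), `para_max` (`frame`, `cell_id`,
#'       `position_um`), `divisions` (`parent_id`, `frame`,
#'       `daughter_new_pole_side`, `daughter_old_pole_side`, `plane_um`,
#'       `larger_daughter`), and `splits` (`cell_id`, `frame`,
#'       `parent_focus_id`, `child_focus_id_1`, `child_focus_id_2`).}
#'     \item{params}{the parameters used.}
#'   }
#' @export
simulate_lineage <- function(params, n_generations) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.numeric(n_generations) || n_generations < 1) {
    stop("'n_generations' must be >= 1", call. = FALSE)
  }
  dt <- params$frame_interval
  rate <- params$elongation_rate
  l_div <- params$division_length
  l_birth0 <- l_div / 2

  cells_rows <- list()
  foci_rows <- list()
  para_rows <- list()
  div_rows <- list()
  split_rows <- list()
  next_cell_id <- 1L
  next_focus_id <- 1L

  new_focus_id <- function() {
    id <- next_focus_id
    next_focus_id <<- next_focus_id + 1L
    id
  }

  # queue entries: one cell at birth, foci as list of (id, x, regime)
  root <- list(
    cell_id = 1L, parent_id = NA_integer_, birth_time = 0,
    birth_length = l_birth0, orient = "left", report_pole = "unknown",
    generation = 1L,
    foci = list(list(id = new_focus_id(), x = 0.5 * l_birth0, regime = "near"))
  )
  next_cell_id <- 2L
  queue <- list(root)

  while (length(queue) > 0L) {
    cell <- queue[[1L]]
    queue <- queue[-1L]
    set.seed(spawn_seed(params$seed, paste0("cell/", cell$cell_id)))

    l0 <- cell$birth_length
    # division at the first frame where the growth law reaches division_length
    n_grow <- ceiling(log(l_div / l0) / (rate * dt) - 1e-9)
    n_grow <- max(1L, as.integer(n_grow))
    k <- 0:n_grow
    lengths <- l0 * exp(rate * k * dt)
    times <- cell$birth_time + k * dt
    frames <- as.integer(round(times / dt))
    n_frames <- length(k)

    is_leaf <- cell$generation >= n_generations

    # seed a focus at midcell if the cell inherited none
    if (length(cell$foci) == 0L) {
      cell$foci <- list(list(id = new_focus_id(), x = 0.5 * l0,
                             regime = "near"))
    }

    # schedule one focus split per cycle
    split_frame_idx <- max(2L, as.integer(round(0.25 * n_frames)))
    did_split <- FALSE

    # pre-draw fGn increment streams for near-regime motion (one per
    # possible focus slot; at most inherited + 2 from the split)
    n_slots <- length(cell$foci) + 2L
    fgn <- fgn_increments(n_slots, n_frames, params$near_regime_hurst,
                          params$near_regime_step)
    slot_of <- seq_along(cell$foci)
    next_slot <- length(cell$foci) + 1L

    foci <- cell$foci
    para_x <- numeric(n_frames)
    foci_frame_rows <- vector("list", n_frames)

    for (i in seq_len(n_frames)) {
      L <- lengths[i]
      # ParA maximum: fixed fraction of length from the new pole;
      # relocated near the division plane at the division frame
      para_x[i] <- params$parA_peak_frac * L

      if (i > 1L) {
        adv <- L / lengths[i - 1L]
        for (j in seq_along(foci)) {
          x <- foci[[j]]$x * adv
          if (foci[[j]]$regime == "far" &&
              abs(x - para_x[i]) > params$regime_switch_distance) {
            x <- x + params$far_regime_speed * dt  # directed to old pole
          } else {
            x <- x + fgn[slot_of[j], i]
          }
          foci[[j]]$x <- clamp_subpolar(x, L)
        }
        foci <- enforce_separation(foci, L)
      }

      if (!did_split && i == split_frame_idx) {
        # the focus nearest midcell splits; the child on the ParA-max side
        # keeps near-regime motion, the other segregates toward the old pole
        mid <- 0.5 * L
        js <- which.min(vapply(foci, function(f) abs(f$x - mid), 0))
        parent_focus <- foci[[js]]
        # sister foci born resolvably apart (they separate within one frame)
        off <- 0.8
        x_near <- clamp_subpolar(parent_focus$x - off, L)
        x_far <- clamp_subpolar(parent_focus$x + off, L)
        id1 <- new_focus_id()
        id2 <- new_focus_id()
        child_near <- list(id = id1, x = x_near, regime = "near")
        child_far <- list(id = id2, x = x_far, regime = "far")
        foci[[js]] <- child_near
        slot_of[js] <- next_slot
        foci[[length(foci) + 1L]] <- child_far
        slot_of[length(foci)] <- next_slot + 1L
        next_slot <- next_slot + 2L
        split_rows[[length(split_rows) + 1L]] <- data.frame(
          cell_id = cell$cell_id, frame = frames[i],
          parent_focus_id = parent_focus$id,
          child_focus_id_1 = id1, child_focus_id_2 = id2
        )
        did_split <- TRUE
      }

      foci_frame_rows[[i]] <- data.frame(
        frame = frames[i], cell_id = cell$cell_id,
        focus_id = vapply(foci, function(f) f$id, 0L),
        position_um = vapply(foci, function(f) f$x, 0)
      )
    }

    if (!is_leaf) {
      L <- lengths[n_frames]
      # asymmetric division plane: larger share jittered, truncated to [0.5, 1)
      repeat {
        s <- stats::rnorm(1L, params$division_asymmetry, 0.03)
        if (s >= 0.5 && s < 0.995) break
      }
      larger_on_new_side <- stats::runif(1L) < 0.5
      p <- if (larger_on_new_side) s * L else (1 - s) * L  # from new pole

      # ParA maximum relocates to the plane (small jitter keeps it off the
      # exact plane so one daughter unambiguously inherits it)
      para_x[n_frames] <- clamp_subpolar(p + stats::rnorm(1L, 0, 0.1), L)

      # partition foci by side of the plane (new-pole side: x < p)
      side_new <- vapply(foci, function(f) f$x < p, TRUE)
      # daughter coordinates from each daughter's own new pole (at the plane)
      foci_new_side <- enforce_separation(lapply(foci[side_new], function(f) {
        list(id = f$id, x = clamp_subpolar(p - f$x, p), regime = "near")
      }), p)
      foci_old_side <- enforce_separation(lapply(foci[!side_new], function(f) {
        list(id = f$id, x = clamp_subpolar(f$x - p, L - p), regime = "near")
      }), L - p)

      # lab-frame segments: for a left-oriented parent the new-pole-side
      # daughter is the left lab segment; mirrored for right orientation
      plane_lab <- if (cell$orient == "left") p else L - p
      d_new_id <- next_cell_id
      d_old_id <- next_cell_id + 1L
      next_cell_id <- next_cell_id + 2L
      # daughter's new pole is the end created at the plane
      orient_left_segment <- "right"
      orient_right_segment <- "left"
      if (cell$orient == "left") {
        orient_new <- orient_left_segment   # new-side daughter = left segment
        orient_old <- orient_right_segment
      } else {
        orient_new <- orient_right_segment  # mirrored
        orient_old <- orient_left_segment
      }

      birth_time_d <- times[n_frames] + dt
      d_new <- list(cell_id = d_new_id, parent_id = cell$cell_id,
                    birth_time = birth_time_d, birth_length = p,
                    orient = orient_new, report_pole = orient_new,
                    generation = cell$generation + 1L, foci = foci_new_side)
      d_old <- list(cell_id = d_old_id, parent_id = cell$cell_id,
                    birth_time = birth_time_d, birth_length = L - p,
                    orient = orient_old, report_pole = orient_old,
                    generation = cell$generation + 1L, foci = foci_old_side)
      queue <- c(queue, list(d_new, d_old))

      div_rows[[length(div_rows) + 1L]] <- data.frame(
        parent_id = cell$cell_id, frame = frames[n_frames],
        daughter_new_pole_side = d_new_id, daughter_old_pole_side = d_old_id,
        plane_um = p,
        larger_daughter = if (p >= L - p) d_new_id else d_old_id
      )
    }

    cells_rows[[length(cells_rows) + 1L]] <- data.frame(
      frame = frames, time_h = times, cell_id = cell$cell_id,
      parent_id = cell$parent_id, length_um = lengths,
      new_pole_end = cell$report_pole
    )
    para_rows[[length(para_rows) + 1L]] <- data.frame(
      frame = frames, cell_id = cell$cell_id, position_um = para_x
    )
    foci_rows[[length(foci_rows) + 1L]] <- do.call(rbind, foci_frame_rows)
  }

  cells <- do.call(rbind, cells_rows)
  cells <- cells[order(cells$frame, cells$cell_id), ]
  rownames(cells) <- NULL
  truth <- list(
    foci = do.call(rbind, foci_rows),
    para_max = do.call(rbind, para_rows),
    divisions = if (length(div_rows)) do.call(rbind, div_rows) else
      data.frame(parent_id = integer(), frame = integer(),
                 daughter_new_pole_side = integer(),
                 daughter_old_pole_side = integer(), plane_um = numeric(),
                 larger_daughter = integer()),
    splits = if (length(split_rows)) do.call(rbind, split_rows) else
      data.frame(cell_id = integer(), frame = integer(),
                 parent_focus_id = integer(), child_focus_id_1 = integer(),
                 child_focus_id_2 = integer())
  )
  structure(list(cells = cells, truth = truth, params = params),
            class = "sim_lineage")
}


# foci (and the relocated ParA maximum) rest at subpolar positions, not on
# the pole: 0.5-0.6 um (10% of length in between) from either end
clamp_subpolar <- function(x, L) {
  margin <- min(0.6, max(0.5, 0.1 * L))
  min(max(x, margin), L - margin)
}

# sister origin regions occupy distinct chromosomal territories: foci that
# drift within 0.8 um of each other are pushed symmetrically apart
enforce_separation <- function(foci, L, sep_min = 0.8) {
  if (length(foci) < 2L) return(foci)
  for (pass in 1:3) {
    ord <- order(vapply(foci, function(f) f$x, 0))
    moved <- FALSE
    for (k in seq_len(length(ord) - 1L)) {
      a <- ord[k]; b <- ord[k + 1L]
      gap <- foci[[b]]$x - foci[[a]]$x
      if (gap < sep_min) {
        push <- (sep_min - gap) / 2
        foci[[a]]$x <- clamp_subpolar(foci[[a]]$x - push, L)
        foci[[b]]$x <- clamp_subpolar(foci[[b]]$x + push, L)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  foci
}
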