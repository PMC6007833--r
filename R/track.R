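#' Link validated foci across frames into tracks
#'
#' Greedy nearest-neighbour linking between consecutive frames using
#' pole-relative pixel positions: a focus in frame `t + 1` is connected to
#' the nearest unclaimed focus in frame `t` of the same cell if their
#' pole-relative distance is at most `link_max_px`; otherwise it starts a
#' new track. Across a cell division, a parent-cell focus is remapped into
#' each daughter's pole-relative frame (using the daughter birth lengths to
#' reconstruct the division plane) before matching, so a track follows its
#' focus into the daughter. Ties are resolved toward the lower position.
#'
#' @param foci validated foci from [detect_foci()].
#' @param cell_table cell table (for daughter geometry at divisions).
#' @param tree a `lineage_tree` built from `cell_table`.
#' @param config a [pipeline_config()] (`link_max_px`).
#' @return data.frame of track points: `track_id`, `cell_id`, `frame`,
#'   `position_px`, `position_um`, `intensity`.
#' @export
link_foci <- function(foci, cell_table, tree, config = pipeline_config()) {
  if (nrow(foci) == 0L) {
    return(data.frame(track_id = integer(0), cell_id = integer(0),
                      frame = integer(0), position_px = numeric(0),
                      position_um = numeric(0), intensity = numeric(0)))
  }
  foci <- foci[order(foci$cell_id, foci$frame, foci$position_px), ]
  foci$track_id <- NA_integer_
  next_track <- 1L

  # process cells parent-before-daughter so cross-division links see
  # already-assigned parent tracks
  order_ids <- unique(cell_table$cell_id[order(cell_table$frame)])

  for (cid in order_ids) {
    rows_cell <- which(foci$cell_id == cid)
    if (!length(rows_cell)) next
    frames <- sort(unique(foci$frame[rows_cell]))

    # seed first frame of this cell: inherit tracks across the division
    prev <- NULL  # data.frame(row, pos_px, track_id)
    parent <- tree$cells$parent_id[match(cid, tree$cells$cell_id)]
    if (!is.na(parent)) {
      pr <- which(foci$cell_id == parent &
                    foci$frame == max(foci$frame[foci$cell_id == parent],
                                      -Inf))
      if (length(pr) && !anyNA(foci$track_id[pr])) {
        mapped <- remap_into_daughter(foci$position_px[pr], parent, cid,
                                      cell_table, tree, config)
        ok <- !is.na(mapped)
        if (any(ok)) {
          prev <- data.frame(row = pr[ok], pos_px = mapped[ok],
                             track_id = foci$track_id[pr[ok]])
        }
      }
    }

    for (fr in frames) {
      cur <- which(foci$cell_id == cid & foci$frame == fr)
      cur <- cur[order(foci$position_px[cur])]
      assigned <- rep(NA_integer_, length(cur))
      if (!is.null(prev) && nrow(prev)) {
        # all candidate pairs within reach, nearest first; ties to the
        # lower current position then lower previous position
        pairs <- expand.grid(i = seq_along(cur), j = seq_len(nrow(prev)))
        pairs$d <- abs(foci$position_px[cur[pairs$i]] - prev$pos_px[pairs$j])
        pairs <- pairs[pairs$d <= config$link_max_px, ]
        pairs <- pairs[order(pairs$d, foci$position_px[cur[pairs$i]],
                             prev$pos_px[pairs$j]), ]
        used_prev <- logical(nrow(prev))
        for (k in seq_len(nrow(pairs))) {
          i <- pairs$i[k]; j <- pairs$j[k]
          if (is.na(assigned[i]) && !used_prev[j]) {
            assigned[i] <- prev$track_id[j]
            used_prev[j] <- TRUE
          }
        }
      }
      for (i in seq_along(cur)) {
        if (is.na(assigned[i])) {
          assigned[i] <- next_track
          next_track <- next_track + 1L
        }
        foci$track_id[cur[i]] <- assigned[i]
      }
      prev <- data.frame(row = cur, pos_px = foci$position_px[cur],
                         track_id = assigned)
    }
  }

  res <- foci[, c("track_id", "cell_id", "frame", "position_px",
                  "position_um", "intensity")]
  res <- res[order(res$track_id, res$frame), ]
  rownames(res) <- NULL
  res
}

#' @keywords internal
remap_into_daughter <- function(pos_px, parent_id, daughter_id, cell_table,
                                tree, config) {
  # reconstruct the division plane from daughter birth lengths; parent
  # positions are pole-relative (new pole when known, else left pole)
  kids <- tree$children[[as.character(parent_id)]]
  if (is.null(kids) || length(kids) != 2L) return(rep(NA_real_, length(pos_px)))
  px <- config$pixel_size_um
  parent_rows <- cell_table[cell_table$cell_id == parent_id, ]
  L <- parent_rows$length_um[which.max(parent_rows$frame)]
  first_len <- function(id) {
    cr <- cell_table[cell_table$cell_id == id, ]
    cr$length_um[which.min(cr$frame)]
  }
  npe_of <- function(id) {
    cell_table$new_pole_end[match(id, cell_table$cell_id)]
  }
  # lab-frame position of the parent's foci
  p_npe <- npe_of(parent_id)
  pos_um <- pos_px * px
  lab <- if (identical(p_npe, "right")) L - pos_um else pos_um
  # daughters' lab segments: the daughter whose new pole faces left sits in
  # the right lab segment (its new pole is the plane on its left)
  d_npe <- vapply(kids, npe_of, "")
  left_kid <- kids[d_npe == "right"][1L]
  right_kid <- kids[d_npe == "left"][1L]
  if (is.na(left_kid) || is.na(right_kid)) {
    # polarity unknown: fall back to ordering by id, left first
    left_kid <- kids[1L]; right_kid <- kids[2L]
  }
  plane <- first_len(left_kid)
  if (daughter_id == left_kid) {
    inside <- lab <= plane
    d_um <- plane - lab       # from the daughter's new pole (the plane)
  } else {
    inside <- lab >= plane
    d_um <- lab - plane
  }
  out <- ifelse(inside, d_um / px, NA_real_)
  as.numeric(out)
}

#' Propose focus split (parent/child) assignments
#'
#' A track ending at frame `t` while two tracks start at frame `t + 1` in
#' the same cell lineage, both within `split_radius_px` of its last
#' position, is proposed as a parent with those two children. More than
#' two candidate children suppresses the proposal (flagged for manual
#' override).
#'
#' @param tracks track table from [link_foci()].
#' @param config a [pipeline_config()] (`split_radius_px`).
#' @return data.frame `parent_track_id`, `child_track_id_1`,
#'   `child_track_id_2`; attribute `"flagged"` lists suppressed parents.
#' @export
assign_splits <- function(tracks, config = pipeline_config()) {
  empty <- data.frame(parent_track_id = integer(0),
                      child_track_id_1 = integer(0),
                      child_track_id_2 = integer(0))
  if (nrow(tracks) == 0L) return(structure(empty, flagged = integer(0)))
  last <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    tr[which.max(tr$frame), ]
  }))
  first <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    tr[which.min(tr$frame), ]
  }))
  out <- list()
  flagged <- integer(0)
  for (k in seq_len(nrow(last))) {
    ends <- last[k, ]
    cand <- first[first$cell_id == ends$cell_id &
                    first$frame == ends$frame + 1L &
                    first$track_id != ends$track_id &
                    abs(first$position_px - ends$position_px) <=
                      config$split_radius_px, ]
    if (nrow(cand) == 2L) {
      out[[length(out) + 1L]] <- data.frame(
        parent_track_id = ends$track_id,
        child_track_id_1 = min(cand$track_id),
        child_track_id_2 = max(cand$track_id)
      )
    } else if (nrow(cand) > 2L) {
      warning(sprintf(
        "track %d: %d candidate children; no automatic split assigned",
        ends$track_id, nrow(cand)))
      flagged <- c(flagged, ends$track_id)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  structure(res, flagged = flagged)
}

#' Apply manual curation overrides to tracks and splits
#'
#' Reproducible stand-in for manual curation: a plain-text command file,
#' one command per line, applied in order.
#' Supported commands:
#' \describe{
#'   \item{`merge A B`}{append track B onto track A (frames must not
#'     overlap); B's id disappears.}
#'   \item{`split_link P C1 C2`}{declare tracks C1 and C2 children of P.}
#'   \item{`split_unlink P`}{remove any split record with parent P.}
#' }
#' Lines starting with `#` and blank lines are ignored. A dangling track id
#' or an override that would put two foci of one track in the same frame is
#' a hard error.
#'
#' @param tracks track table from [link_foci()].
#' @param splits split table from [assign_splits()].
#' @param override_file path to the command file (or `NULL` for identity).
#' @return list `tracks`, `splits` after overrides.
#' @export
apply_overrides <- function(tracks, splits, override_file = NULL) {
  if (is.null(override_file)) return(list(tracks = tracks, splits = splits))
  lines <- readLines(override_file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  known <- function(id) id %in% tracks$track_id
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1L]]
    cmd <- tok[1L]
    args <- suppressWarnings(as.integer(tok[-1L]))
    if (anyNA(args)) stop("malformed override line: ", ln, call. = FALSE)
    if (cmd == "merge") {
      if (length(args) != 2L || !all(vapply(args, known, TRUE))) {
        stop("merge references unknown track id in: ", ln, call. = FALSE)
      }
      a <- args[1L]; b <- args[2L]
      fa <- tracks$frame[tracks$track_id == a]
      fb <- tracks$frame[tracks$track_id == b]
      if (length(intersect(fa, fb))) {
        stop(sprintf(
          "merge %d %d would put two foci of one track in the same frame",
          a, b), call. = FALSE)
      }
      tracks$track_id[tracks$track_id == b] <- a
      splits$parent_track_id[splits$parent_track_id == b] <- a
      splits$child_track_id_1[splits$child_track_id_1 == b] <- a
      splits$child_track_id_2[splits$child_track_id_2 == b] <- a
    } else if (cmd == "split_link") {
      if (length(args) != 3L || !all(vapply(args, known, TRUE))) {
        stop("split_link references unknown track id in: ", ln, call. = FALSE)
      }
      splits <- splits[splits$parent_track_id != args[1L], ]
      splits <- rbind(splits, data.frame(
        parent_track_id = args[1L],
        child_track_id_1 = args[2L], child_track_id_2 = args[3L]))
    } else if (cmd == "split_unlink") {
      if (length(args) != 1L || !known(args[1L])) {
        stop("split_unlink references unknown track id in: ", ln,
             call. = FALSE)
      }
      splits <- splits[splits$parent_track_id != args[1L], ]
    } else {
      stop("unknown override command: ", cmd, call. = FALSE)
    }
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  rownames(splits) <- NULL
  list(tracks = tracks, splits = splits)
}
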