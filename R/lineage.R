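#' Build a lineage tree from a cell table
#'
#' Links per-frame cell records into a tree via `parent_id`. Cells whose
#' parent never appears in the table become roots (with a warning). A
#' parent with a number of daughters other than two is flagged.
#'
#' @param cell_table data.frame with columns `frame`, `time_h`, `cell_id`,
#'   `parent_id`, `length_um`, `new_pole_end`.
#' @return a list of class `lineage_tree`: `cells` (the table, ordered by
#'   cell then frame), `children` (named list: parent id -> daughter ids),
#'   `roots` (cell ids), `inconsistencies` (character vector of flags).
#' @export
build_lineage <- function(cell_table) {
  stopifnot(is.data.frame(cell_table))
  ct <- cell_table[order(cell_table$cell_id, cell_table$frame), ]
  rownames(ct) <- NULL
  ids <- unique(ct$cell_id)
  first <- ct[!duplicated(ct$cell_id), c("cell_id", "parent_id")]
  has_parent <- !is.na(first$parent_id)
  orphan <- has_parent & !(first$parent_id %in% ids)
  if (any(orphan)) {
    warning(sprintf("%d cell(s) reference an absent parent; treated as roots",
                    sum(orphan)))
  }
  attached <- has_parent & !orphan
  children <- split(first$cell_id[attached], first$parent_id[attached])
  inconsistencies <- character(0)
  bad <- names(children)[vapply(children, length, 0L) != 2L]
  if (length(bad)) {
    inconsistencies <- sprintf("parent %s has %d daughter(s), expected 2",
                               bad,
                               vapply(children[bad], length, 0L))
    warning(paste(inconsistencies, collapse = "; "))
  }
  roots <- first$cell_id[!attached]
  structure(list(cells = ct, children = children, roots = roots,
                 inconsistencies = inconsistencies),
            class = "lineage_tree")
}

#' Exponential growth rate of one cell
#'
#' Ordinary least-squares slope of `ln(length)` against time — the
#' elongation rate of exponential growth, with its standard error.
#'
#' @param time_h time points, h.
#' @param length_um cell lengths, um (> 0).
#' @return list with `rate` (1/h) and `se`; both `NA` with fewer than 3
#'   frames.
#' @export
growth_rate <- function(time_h, length_um) {
  keep <- is.finite(time_h) & is.finite(length_um) & length_um > 0
  time_h <- time_h[keep]
  length_um <- length_um[keep]
  if (length(time_h) < 3L) return(list(rate = NA_real_, se = NA_real_))
  fit <- stats::lm(log(length_um) ~ time_h)
  co <- suppressWarnings(summary(fit))$coefficients
  list(rate = unname(co["time_h", "Estimate"]),
       se = unname(co["time_h", "Std. Error"]))
}

#' Doubling time of one cell
#'
#' Time from birth to division. Defined only for cells whose birth is
#' observed (they have a parent) and that divide within the movie (they
#' have daughters).
#'
#' @param tree a `lineage_tree`.
#' @param cell_id cell id.
#' @return doubling time in h, or `NA` if birth or division is unobserved.
#' @export
doubling_time <- function(tree, cell_id) {
  ct <- tree$cells[tree$cells$cell_id == cell_id, ]
  if (nrow(ct) == 0L) return(NA_real_)
  born <- !is.na(ct$parent_id[1L])
  divides <- as.character(cell_id) %in% names(tree$children)
  if (!born || !divides) return(NA_real_)
  max(ct$time_h) - min(ct$time_h)
}

#' Assign new/old pole identity down a lineage tree
#'
#' Each daughter's new pole is the end created at the division plane: the
#' daughter occupying the left lab segment of its parent gets
#' `new_pole_end = "right"` and vice versa. Roots keep `"unknown"`.
#' Daughter sides are inferred from the recorded `new_pole_end` when
#' present, else left blank for manual curation.
#'
#' @param tree a `lineage_tree`.
#' @param daughter_sides optional data.frame (`cell_id`, `side` in
#'   `{"left", "right"}`) giving each daughter's lab segment within its
#'   parent; when supplied it overrides the table's `new_pole_end`.
#' @return the tree with `new_pole_end` filled in `tree$cells`.
#' @export
assign_polarity <- function(tree, daughter_sides = NULL) {
  ct <- tree$cells
  if (!is.null(daughter_sides)) {
    for (i in seq_len(nrow(daughter_sides))) {
      id <- daughter_sides$cell_id[i]
      side <- daughter_sides$side[i]
      # new pole faces the plane: left-segment daughter -> right end
      ct$new_pole_end[ct$cell_id == id] <-
        if (identical(side, "left")) "right" else "left"
    }
  }
  ct$new_pole_end[ct$cell_id %in% tree$roots &
                    !(ct$new_pole_end %in% c("left", "right"))] <- "unknown"
  tree$cells <- ct
  tree
}

#' Minicell classification
#'
#' @param length_um cell length, um (vectorised).
#' @param max_um inclusive cutoff, um.
#' @return logical: `TRUE` for minicells (`length <= max_um`).
#' @export
classify_minicell <- function(length_um, max_um = 2.25) {
  stopifnot(all(length_um > 0, na.rm = TRUE))
  length_um <= max_um
}

#' Per-cell summary statistics for a lineage
#'
#' @param tree a `lineage_tree`.
#' @param minicell_max_um minicell cutoff passed to [classify_minicell()].
#' @param minicell_mode `"birth"` applies the cutoff to birth length,
#'   `"snapshot"` to the maximum observed length.
#' @return data.frame: `cell_id`, `parent_id`, `birth_length_um`,
#'   `division_length_um`, `growth_rate`, `growth_rate_se`,
#'   `doubling_time_h`, `is_minicell`.
#' @export
cell_statistics <- function(tree, minicell_max_um = 2.25,
                            minicell_mode = c("birth", "snapshot")) {
  minicell_mode <- match.arg(minicell_mode)
  ids <- unique(tree$cells$cell_id)
  rows <- lapply(ids, function(id) {
    ct <- tree$cells[tree$cells$cell_id == id, ]
    ct <- ct[order(ct$frame), ]
    gr <- growth_rate(ct$time_h, ct$length_um)
    divides <- as.character(id) %in% names(tree$children)
    ref_len <- if (minicell_mode == "birth") ct$length_um[1L]
               else max(ct$length_um)
    data.frame(
      cell_id = id, parent_id = ct$parent_id[1L],
      birth_length_um = ct$length_um[1L],
      division_length_um = if (divides) ct$length_um[nrow(ct)] else NA_real_,
      growth_rate = gr$rate, growth_rate_se = gr$se,
      doubling_time_h = doubling_time(tree, id),
      is_minicell = classify_minicell(ref_len, minicell_max_um)
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
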