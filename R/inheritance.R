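#' Per-sibling-pair ParA inheritance attributes
#'
#' For every division in a lineage with both daughters observed at birth,
#' computes each daughter's total ParA (sum of pixel intensities at the
#' birth frame), maximum ParA (maximum pixel intensity), birth length and
#' area (length times a nominal cell width), and growth rate, and labels
#' the high/low total inheritor and the larger/smaller sibling.
#'
#' @param tree a `lineage_tree`.
#' @param profiles profile table (raw intensities are summed; column
#'   `parA_intensity`).
#' @param nominal_width_um nominal rod width used to convert length to
#'   area, um.
#' @return data.frame, one row per division: ids, per-daughter totals,
#'   maxima, birth lengths/areas, growth rates, and labels
#'   `high_total_inheritor`, `larger_sibling` (`NA` when tied).
#' @export
sibling_attributes <- function(tree, profiles, nominal_width_um = 0.5) {
  rows <- list()
  for (parent in names(tree$children)) {
    kids <- tree$children[[parent]]
    if (length(kids) != 2L) next
    d1 <- kids[1L]; d2 <- kids[2L]
    att <- lapply(c(d1, d2), function(id) {
      ct <- tree$cells[tree$cells$cell_id == id, ]
      ct <- ct[order(ct$frame), ]
      birth_frame <- ct$frame[1L]
      pr <- profiles[profiles$cell_id == id & profiles$frame == birth_frame, ]
      if (nrow(pr) == 0L) return(NULL)
      gr <- growth_rate(ct$time_h, ct$length_um)
      list(total = sum(pr$parA_intensity), max = max(pr$parA_intensity),
           length = ct$length_um[1L],
           area = ct$length_um[1L] * nominal_width_um, rate = gr$rate)
    })
    if (is.null(att[[1L]]) || is.null(att[[2L]])) next  # pair excluded
    a <- att[[1L]]; b <- att[[2L]]
    rows[[length(rows) + 1L]] <- data.frame(
      parent_id = as.integer(parent), daughter_1 = d1, daughter_2 = d2,
      total_1 = a$total, total_2 = b$total,
      max_1 = a$max, max_2 = b$max,
      birth_length_1 = a$length, birth_length_2 = b$length,
      birth_area_1 = a$area, birth_area_2 = b$area,
      growth_rate_1 = a$rate, growth_rate_2 = b$rate,
      high_total_inheritor = if (a$total > b$total) d1
                             else if (b$total > a$total) d2 else NA_integer_,
      larger_sibling = if (a$length > b$length) d1
                       else if (b$length > a$length) d2 else NA_integer_
    )
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_id = integer(0))
  rownames(res) <- NULL
  res
}

#' Which daughter inherits the parent's ParA maximum region
#'
#' The parent's ParA maximum position at its last pre-division frame is
#' compared with the division plane (reconstructed from the daughters'
#' birth lengths, in the parent's lab frame): the daughter whose axial
#' interval contains the maximum inherits it. A maximum exactly on the
#' plane goes to the larger daughter (flagged).
#'
#' @param max_lab_um parent ParA maximum position in the parent lab frame,
#'   um from the lab-left pole.
#' @param plane_lab_um division plane position, um from the lab-left pole.
#' @param left_daughter,right_daughter ids of the daughters occupying the
#'   left and right lab segments.
#' @param left_length,right_length daughter birth lengths, um.
#' @return list: `inheritor` (daughter id), `tie` (logical flag).
#' @export
classify_max_inheritor <- function(max_lab_um, plane_lab_um,
                                   left_daughter, right_daughter,
                                   left_length, right_length) {
  if (max_lab_um < plane_lab_um) {
    list(inheritor = left_daughter, tie = FALSE)
  } else if (max_lab_um > plane_lab_um) {
    list(inheritor = right_daughter, tie = FALSE)
  } else {
    larger <- if (left_length >= right_length) left_daughter else right_daughter
    list(inheritor = larger, tie = TRUE)
  }
}

#' Size-based null prediction for ParA-maximum inheritance
#'
#' Under random placement, the probability that a daughter inherits the
#' parent's maximum equals its share of the parent's size, operationalised
#' as the daughter's size over the sum of the two daughters' birth sizes
#' (so the two probabilities sum to exactly 1 per division). Summing the
#' larger daughter's share over divisions predicts how many maxima the
#' larger siblings should inherit by size alone; the binomial-style
#' standard error `sqrt(sum p_i (1 - p_i))` accompanies it.
#'
#' @param size_larger,size_smaller per-division birth sizes of the larger
#'   and smaller daughter (any consistent units; zero sizes excluded).
#' @param observed_larger_count observed number of divisions in which the
#'   larger daughter inherited the maximum (optional).
#' @return list: `n_divisions`, `expected_larger_count`, `se`,
#'   `observed_larger_count`, `probabilities` (per-division larger-share).
#' @export
predict_random_inheritance <- function(size_larger, size_smaller,
                                       observed_larger_count = NA_integer_) {
  stopifnot(length(size_larger) == length(size_smaller))
  ok <- size_larger > 0 & size_smaller > 0
  size_larger <- size_larger[ok]
  size_smaller <- size_smaller[ok]
  p <- size_larger / (size_larger + size_smaller)
  list(n_divisions = length(p),
       expected_larger_count = sum(p),
       se = sqrt(sum(p * (1 - p))),
       observed_larger_count = observed_larger_count,
       probabilities = p)
}

#' Compare high- vs low-inheritor groups on a paired attribute
#'
#' Reports both the paired Wilcoxon signed-rank test and Welch's t-test
#' (the two tests the analysis tradition uses interchangeably for related
#' sibling samples), with group means.
#'
#' @param high,low attribute values for the high- and low-inheritor
#'   sibling of each pair (equal length, pairs with missing values
#'   dropped).
#' @return list: `n_pairs`, `mean_high`, `mean_low`, `wilcoxon_p`,
#'   `wilcoxon_statistic`, `welch_p`, `welch_statistic`; Wilcoxon fields
#'   `NA` (with a note) when all pairs tie.
#' @export
compare_inheritor_groups <- function(high, low) {
  stopifnot(length(high) == length(low))
  keep <- is.finite(high) & is.finite(low)
  high <- high[keep]
  low <- low[keep]
  if (length(high) < 6L) {
    stop("need at least 6 complete pairs", call. = FALSE)
  }
  wt <- tryCatch(
    stats::wilcox.test(high, low, paired = TRUE, exact = FALSE),
    error = function(e) NULL)
  all_tied <- all(high == low)
  tt <- tryCatch(stats::t.test(high, low, var.equal = FALSE),
                 error = function(e) NULL)
  list(
    n_pairs = length(high),
    mean_high = mean(high), mean_low = mean(low),
    wilcoxon_p = if (all_tied || is.null(wt)) NA_real_ else wt$p.value,
    wilcoxon_statistic = if (all_tied || is.null(wt)) NA_real_
                         else unname(wt$statistic),
    welch_p = if (is.null(tt)) NA_real_ else tt$p.value,
    welch_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    note = if (all_tied) "all pairs tied; both tests degenerate" else
      if (is.null(tt)) "zero-variance data; Welch undefined" else NULL
  )
}

#' Exact paired Wilcoxon signed-rank test (small n)
#'
#' Exact one- and two-sided p-values by full enumeration of the `2^n` sign
#' assignments of the nonzero paired differences. Used for small samples
#' where the normal approximation is poor, and as the reference the
#' large-sample path is checked against.
#'
#' @param high,low paired values.
#' @return list: `statistic` (V, sum of positive-difference ranks),
#'   `p_greater`, `p_two_sided`, `n_nonzero`.
#' @export
wilcoxon_signed_rank_exact <- function(high, low) {
  d <- high - low
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all pairs tied", call. = FALSE)
  if (n > 20L) stop("exact enumeration limited to n <= 20", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  list(statistic = v,
       p_greater = mean(vs >= v),
       p_two_sided = min(1, 2 * min(mean(vs >= v), mean(vs <= v))),
       n_nonzero = n)
}

#' Kruskal-Wallis rank ANOVA with Dunn's post-hoc comparisons
#'
#' Rank-based one-way analysis of variance across groups (tie-corrected H
#' via [stats::kruskal.test()]) followed by Dunn's all-pairwise z tests on
#' rank sums with Bonferroni-adjusted p-values, and a letter display
#' clustering groups whose pairwise differences are non-significant.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor).
#' @param alpha significance level for the letter clustering.
#' @param min_n groups with fewer observations are excluded (warning).
#' @return list: `kruskal` (`H`, `df`, `p`), `dunn` (data.frame
#'   `group_1`, `group_2`, `z`, `p_unadjusted`, `p_adjusted`),
#'   `letters` (named character vector of group letter classes),
#'   `excluded` (dropped group labels).
#' @export
compare_size_distributions <- function(values, groups, alpha = 0.05,
                                       min_n = 5L) {
  groups <- factor(groups)
  keep_groups <- names(which(table(groups) >= min_n))
  excluded <- setdiff(levels(groups), keep_groups)
  if (length(excluded)) {
    warning("groups excluded (fewer than ", min_n, " observations): ",
            paste(excluded, collapse = ", "))
  }
  sel <- groups %in% keep_groups
  values <- values[sel]
  groups <- droplevels(groups[sel])
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)

  kt <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  # tie correction term for the Dunn standard error
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  n_pairs <- ncol(pairs)
  z <- p_un <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / ns[[g1]] + 1 / ns[[g2]]))
    z[k] <- (rbar[[g1]] - rbar[[g2]]) / se
    p_un[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- pmin(1, p_un * n_pairs)  # Bonferroni over all pairs
  dunn <- data.frame(group_1 = pairs[1L, ], group_2 = pairs[2L, ],
                     z = z, p_unadjusted = p_un, p_adjusted = p_adj)

  # letter display: greedy clustering by median rank; groups joined when
  # their pairwise difference is non-significant with every member
  ord <- names(sort(vapply(lv, function(g) rbar[[g]], 0), decreasing = TRUE))
  sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (k in seq_len(n_pairs)) {
    s <- p_adj[k] < alpha
    sig[pairs[1L, k], pairs[2L, k]] <- s
    sig[pairs[2L, k], pairs[1L, k]] <- s
  }
  classes <- list()
  for (g in ord) {
    placed <- FALSE
    for (ci in seq_along(classes)) {
      if (!any(sig[g, classes[[ci]]])) {
        classes[[ci]] <- c(classes[[ci]], g)
        placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- g
  }
  letters_out <- stats::setNames(rep("", length(lv)), lv)
  for (ci in seq_along(classes)) {
    for (g in classes[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], LETTERS[ci])
    }
  }
  list(kruskal = list(H = unname(kt$statistic), df = unname(kt$parameter),
                      p = kt$p.value),
       dunn = dunn, letters = letters_out, excluded = excluded)
}

#' ParA-maximum inheritance across all divisions of a movie
#'
#' Applies [classify_max_inheritor()] to every division: the parent's ParA
#' maximum at its last frame (converted to the parent lab frame) is
#' compared with the division plane reconstructed from daughter birth
#' lengths, and the inheritor is recorded next to the larger sibling.
#'
#' @param tree a `lineage_tree`.
#' @param para_max per-frame ParA maxima (`cell_id`, `frame`,
#'   `position_um`, pole-relative as from [smooth_movie()]).
#' @param config a [pipeline_config()].
#' @return data.frame, one row per division: `parent_id`,
#'   `left_daughter`, `right_daughter`, `plane_lab_um`, `max_lab_um`,
#'   `inheritor`, `larger_sibling`, `larger_inherits`, `tie`.
#' @export
max_inheritance_table <- function(tree, para_max, config = pipeline_config()) {
  ct <- tree$cells
  rows <- list()
  for (parent in names(tree$children)) {
    kids <- tree$children[[parent]]
    if (length(kids) != 2L) next
    pid <- as.integer(parent)
    prow <- ct[ct$cell_id == pid, ]
    last_frame <- max(prow$frame)
    L <- prow$length_um[prow$frame == last_frame][1L]
    pm <- para_max[para_max$cell_id == pid & para_max$frame == last_frame, ]
    if (nrow(pm) == 0L || !is.finite(pm$position_um[1L])) next
    npe <- prow$new_pole_end[1L]
    max_lab <- if (identical(npe, "right")) L - pm$position_um[1L]
               else pm$position_um[1L]
    npe_k <- vapply(kids, function(id)
      ct$new_pole_end[match(id, ct$cell_id)], "")
    left_kid <- kids[npe_k == "right"][1L]
    right_kid <- kids[npe_k == "left"][1L]
    if (is.na(left_kid) || is.na(right_kid)) {
      left_kid <- kids[1L]; right_kid <- kids[2L]
    }
    len_of <- function(id) {
      cr <- ct[ct$cell_id == id, ]
      cr$length_um[which.min(cr$frame)]
    }
    l_len <- len_of(left_kid)
    r_len <- len_of(right_kid)
    cls <- classify_max_inheritor(max_lab, l_len, left_kid, right_kid,
                                  l_len, r_len)
    larger <- if (l_len >= r_len) left_kid else right_kid
    rows[[length(rows) + 1L]] <- data.frame(
      parent_id = pid, left_daughter = left_kid, right_daughter = right_kid,
      plane_lab_um = l_len, max_lab_um = max_lab,
      inheritor = cls$inheritor, larger_sibling = larger,
      larger_inherits = cls$inheritor == larger, tie = cls$tie
    )
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_id = integer(0))
  rownames(res) <- NULL
  res
}
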