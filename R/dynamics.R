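#' Distance series between a focus track and the ParA maximum
#'
#' Unsigned axial distance between a focus and the per-frame ParA maximum
#' of its cell, on the frames where both are defined. The landmark itself
#' moves, so displacements mix focus and landmark motion — deliberately,
#' since the quantity of interest is the focus's position relative to the
#' ParA gradient.
#'
#' @param track one track's points (`cell_id`, `frame`, `position_um`).
#' @param para_max per-frame maxima (`cell_id`, `frame`, `position_um`).
#' @return data.frame `frame`, `time_idx` (0-based frame offset),
#'   `distance_um`; zero rows if no overlapping frames.
#' @export
distance_to_para_max <- function(track, para_max) {
  m <- merge(track, para_max, by = c("cell_id", "frame"),
             suffixes = c("_focus", "_max"))
  m <- m[is.finite(m$position_um_max), ]
  m <- m[order(m$frame), ]
  if (nrow(m) == 0L) {
    return(data.frame(frame = integer(0), time_idx = integer(0),
                      distance_um = numeric(0)))
  }
  data.frame(frame = m$frame,
             time_idx = m$frame - m$frame[1L],
             distance_um = abs(m$position_um_focus - m$position_um_max))
}

#' Binned mean squared displacement of distance series
#'
#' For every ordered pair of time points `(t, t + dt)` within a series the
#' displacement `dx = d(t + dt) - d(t)` is computed (all overlapping
#' windows). A series contributes all its pairs to the single bin chosen by
#' its distance at first observation; series starting beyond the last bin
#' edge are discarded. Per bin and lag the mean of `dx^2`, its
#' t-distribution 95% confidence interval, and the pair count are reported.
#'
#' @param series_list list of numeric distance vectors (one per track),
#'   frames assumed consecutive at `frame_interval` spacing.
#' @param bin_edges_um bin edges, um (half-open bins `[lo, hi)`).
#' @param frame_interval h per frame.
#' @param conf confidence level for the interval.
#' @return data.frame of class `msd_result`: `bin` (label), `bin_lo`,
#'   `bin_hi`, `dt_h`, `msd_um2`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
msd_binned <- function(series_list, bin_edges_um = c(0, 1.5, 3, 4.5),
                       frame_interval = 0.25, conf = 0.95) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  n_bins <- length(bin_edges_um) - 1L
  labels <- sprintf("[%g,%g)", bin_edges_um[-length(bin_edges_um)],
                    bin_edges_um[-1L])
  max_len <- max(vapply(series_list, length, 0L))
  if (max_len < 2L) stop("every series has fewer than 2 points", call. = FALSE)
  acc <- lapply(seq_len(n_bins), function(b) vector("list", max_len - 1L))
  for (s in series_list) {
    if (length(s) < 2L) next
    d0 <- s[1L]
    bin <- findInterval(d0, bin_edges_um, rightmost.closed = FALSE)
    if (bin < 1L || bin > n_bins) next  # beyond the last edge: discarded
    n <- length(s)
    for (lag in seq_len(n - 1L)) {
      dx <- s[(1L + lag):n] - s[1L:(n - lag)]
      acc[[bin]][[lag]] <- c(acc[[bin]][[lag]], dx^2)
    }
  }
  rows <- list()
  for (b in seq_len(n_bins)) {
    for (lag in seq_len(max_len - 1L)) {
      v <- if (lag <= length(acc[[b]])) acc[[b]][[lag]] else NULL
      n_pairs <- length(v)
      if (n_pairs == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          bin = labels[b], bin_lo = bin_edges_um[b],
          bin_hi = bin_edges_um[b + 1L], dt_h = lag * frame_interval,
          msd_um2 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          n_pairs = 0L)
        next
      }
      m <- mean(v)
      if (n_pairs >= 2L && stats::sd(v) > 0) {
        half <- stats::qt(1 - (1 - conf) / 2, df = n_pairs - 1L) *
          stats::sd(v) / sqrt(n_pairs)
      } else {
        half <- 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        bin = labels[b], bin_lo = bin_edges_um[b],
        bin_hi = bin_edges_um[b + 1L], dt_h = lag * frame_interval,
        msd_um2 = m, ci_low = m - half, ci_high = m + half,
        n_pairs = n_pairs)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("msd_result", class(res))
  res
}

#' Power-law fit of an MSD curve
#'
#' Ordinary least squares on `ln<dx^2> = ln(2D) + beta * ln(dt)`, the
#' anomalous-diffusion model `<dx^2> = 2 D dt^beta`. Non-positive means are
#' excluded (their log is undefined); fewer than 3 usable lags leaves the
#' fit undefined. The motion regime follows the exponent: `beta < 1`
#' sub-diffusive, `beta = 1` free diffusion, `beta > 1` active transport
#' (labelled at a small tolerance around 1).
#'
#' @param dt_h lag times, h.
#' @param msd_um2 mean squared displacements, um^2.
#' @param max_lag_frac use only lags up to this fraction of the largest
#'   lag count (guards single-pair tail means); `1` uses all.
#' @param beta_tol half-width of the "free" band around `beta = 1` for the
#'   regime label.
#' @return list of class `powerlaw_fit`: `D`, `beta`, `se_D`, `se_beta`,
#'   `regime`, `n_lags`; `NA` fields if undefined.
#' @export
fit_powerlaw <- function(dt_h, msd_um2, max_lag_frac = 1, beta_tol = 0.1) {
  stopifnot(length(dt_h) == length(msd_um2))
  keep <- is.finite(dt_h) & is.finite(msd_um2) & dt_h > 0 & msd_um2 > 0
  dt_h <- dt_h[keep]
  msd_um2 <- msd_um2[keep]
  if (length(dt_h) && max_lag_frac < 1) {
    cut <- stats::quantile(dt_h, max_lag_frac, names = FALSE, type = 1L)
    sel <- dt_h <= cut
    dt_h <- dt_h[sel]
    msd_um2 <- msd_um2[sel]
  }
  und <- list(D = NA_real_, beta = NA_real_, se_D = NA_real_,
              se_beta = NA_real_, regime = NA_character_,
              n_lags = length(dt_h))
  class(und) <- "powerlaw_fit"
  if (length(unique(dt_h)) < 3L) return(und)
  fit <- stats::lm(log(msd_um2) ~ log(dt_h))
  co <- suppressWarnings(summary(fit))$coefficients
  beta <- unname(co[2L, "Estimate"])
  se_beta <- unname(co[2L, "Std. Error"])
  ln2D <- unname(co[1L, "Estimate"])
  D <- exp(ln2D) / 2
  se_D <- D * unname(co[1L, "Std. Error"])  # delta method on ln(2D)
  regime <- if (beta < 1 - beta_tol) "subdiffusive"
            else if (beta > 1 + beta_tol) "active"
            else "free"
  structure(list(D = D, beta = beta, se_D = se_D, se_beta = se_beta,
                 regime = regime, n_lags = length(dt_h)),
            class = "powerlaw_fit")
}

#' Fit the MSD power law per distance bin
#'
#' @param msd an `msd_result` from [msd_binned()].
#' @param max_lag_frac passed to [fit_powerlaw()]; defaults to half the
#'   available lags.
#' @return data.frame: `bin`, `D`, `beta`, `se_D`, `se_beta`, `regime`,
#'   `n_lags`.
#' @export
fit_powerlaw_bins <- function(msd, max_lag_frac = 0.5) {
  parts <- split(msd, msd$bin)
  rows <- lapply(names(parts), function(b) {
    p <- parts[[b]]
    f <- fit_powerlaw(p$dt_h, p$msd_um2, max_lag_frac = max_lag_frac)
    data.frame(bin = b, D = f$D, beta = f$beta, se_D = f$se_D,
               se_beta = f$se_beta,
               regime = f$regime %||% NA_character_, n_lags = f$n_lags)
  })
  res <- do.call(rbind, rows)
  res[order(res$bin), , drop = FALSE]
}

#' Classify a focus's velocity relative to the ParA maximum
#'
#' OLS slope of distance against time; slopes below `-threshold` move
#' *toward* the maximum, above `+threshold` *away*, otherwise *with* it.
#'
#' @param time_h time points, h.
#' @param distance_um distances to the ParA maximum, um.
#' @param threshold classification threshold, um/h.
#' @return list: `slope` (um/h), `class` (`"toward"`, `"with"`, `"away"`,
#'   or `NA` with fewer than 3 points).
#' @export
classify_velocity <- function(time_h, distance_um, threshold = 0.15) {
  keep <- is.finite(time_h) & is.finite(distance_um)
  time_h <- time_h[keep]
  distance_um <- distance_um[keep]
  if (length(time_h) < 3L) {
    return(list(slope = NA_real_, class = NA_character_))
  }
  slope <- unname(stats::coef(stats::lm(distance_um ~ time_h))[2L])
  cls <- if (slope < -threshold) "toward"
         else if (slope > threshold) "away"
         else "with"
  list(slope = slope, class = cls)
}

#' Summarise velocity classes
#'
#' @param classes character vector of `"toward"`/`"with"`/`"away"` labels
#'   (`NA`s dropped).
#' @return data.frame `class`, `n`, `fraction`, with attribute
#'   `"toward_or_with"` giving the combined toward-plus-with fraction.
#' @export
summarize_directionality <- function(classes) {
  classes <- classes[!is.na(classes)]
  stopifnot(length(classes) >= 1L)
  lv <- c("toward", "with", "away")
  n <- vapply(lv, function(l) sum(classes == l), 0L)
  res <- data.frame(class = lv, n = as.integer(n),
                    fraction = as.numeric(n) / length(classes))
  attr(res, "toward_or_with") <- sum(n[c("toward", "with")]) / length(classes)
  res
}
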