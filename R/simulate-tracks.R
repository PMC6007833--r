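#' Closed-form autocovariance of fractional Gaussian noise
#'
#' Autocovariance at lag `k` of increments of fractional Brownian motion
#' with Hurst exponent `H` and per-step scale `step_scale`:
#' `(step_scale^2 / 2) * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H))`.
#'
#' @param k integer lag (vectorised).
#' @param hurst Hurst exponent in (0, 1).
#' @param step_scale per-step standard deviation, um.
#' @return autocovariance values.
#' @export
fgn_autocovariance <- function(k, hurst, step_scale = 1) {
  assert_scalar_num(hurst, "hurst", lower = 0, upper = 1,
                    lower_open = TRUE, upper_open = TRUE)
  k <- abs(k)
  h2 <- 2 * hurst
  (step_scale^2 / 2) * (abs(k + 1)^h2 - 2 * k^h2 + abs(k - 1)^h2)
}

#' @keywords internal
fgn_increments <- function(n_tracks, n_steps, hurst, step_scale) {
  # exact sampling by Cholesky factorisation of the closed-form covariance;
  # tracks are short (tens of steps) so O(n^3) is immaterial
  acov <- fgn_autocovariance(0:(n_steps - 1), hurst, step_scale)
  sigma <- stats::toeplitz(acov)
  ch <- chol(sigma)
  z <- matrix(stats::rnorm(n_tracks * n_steps), n_tracks, n_steps)
  z %*% ch
}

#' Simulate 1-D position series in a given motion regime
#'
#' Generates ensembles of the three motion classes an MSD power-law fit
#' must distinguish: sub-diffusive (fractional Gaussian increments, MSD
#' exponent `2 * hurst`), free Brownian (independent Gaussian increments,
#' exponent 1), and ballistic (constant drift, zero noise, exponent 2).
#' All tracks start at position 0.
#'
#' @param regime `"subdiffusive"`, `"brownian"`, or `"ballistic"`.
#' @param n_tracks number of tracks.
#' @param n_steps number of positions per track (>= 3).
#' @param dt frame interval, h.
#' @param step_scale per-step displacement scale, um (sd of one increment
#'   for the stochastic regimes).
#' @param hurst Hurst exponent for `regime = "subdiffusive"`.
#' @param speed drift speed in um/h for `regime = "ballistic"`.
#' @param seed integer seed.
#' @return a numeric matrix, `n_tracks` rows by `n_steps` columns, of
#'   positions; attribute `"dt"` carries the frame interval.
#' @examples
#' tr <- simulate_tracks("ballistic", n_tracks = 1, n_steps = 10,
#'                       dt = 0.25, speed = 0.5)
#' tr[1, 1:3]  # 0.000 0.125 0.250
#' @export
simulate_tracks <- function(regime = c("subdiffusive", "brownian", "ballistic"),
                            n_tracks, n_steps, dt, step_scale = 0.1,
                            hurst = 0.2, speed = 0.5, seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(n_tracks >= 1, n_steps >= 3)
  assert_scalar_num(dt, "dt", lower = 0, lower_open = TRUE)
  if (!is.null(seed)) set.seed(seed)
  inc <- switch(regime,
    subdiffusive = fgn_increments(n_tracks, n_steps - 1L, hurst, step_scale),
    brownian = matrix(stats::rnorm(n_tracks * (n_steps - 1L), sd = step_scale),
                      n_tracks, n_steps - 1L),
    ballistic = matrix(speed * dt, n_tracks, n_steps - 1L)
  )
  pos <- cbind(0, t(apply(inc, 1L, cumsum)))
  dimnames(pos) <- NULL
  attr(pos, "dt") <- dt
  pos
}

#' Simulate confined (mean-reverting) 1-D distance series
#'
#' Discrete Ornstein-Uhlenbeck-style motion: each step pulls the position
#' back toward `center` by a fraction `rate`, plus Gaussian noise. The MSD
#' of such confined motion saturates, so its fitted anomalous exponent
#' falls below 1 — the bounded regime complementing [simulate_tracks()].
#'
#' @param n_tracks number of series.
#' @param n_steps positions per series (>= 3).
#' @param center attractor position, um.
#' @param rate reversion fraction per frame, in `(0, 1]`.
#' @param noise_sd per-step noise, um.
#' @param seed integer seed.
#' @return numeric matrix, `n_tracks` by `n_steps`, starting at `center`.
#' @export
simulate_confined <- function(n_tracks, n_steps, center = 1, rate = 0.5,
                              noise_sd = 0.1, seed = NULL) {
  stopifnot(n_tracks >= 1, n_steps >= 3)
  assert_scalar_num(rate, "rate", lower = 0, upper = 1, lower_open = TRUE)
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(0, n_tracks, n_steps)
  pos[, 1] <- center
  for (j in 2:n_steps) {
    pos[, j] <- pos[, j - 1] + rate * (center - pos[, j - 1]) +
      stats::rnorm(n_tracks, 0, noise_sd)
  }
  pos
}
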