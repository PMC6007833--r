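# independent oracles and shared fixtures, built in code

# dense-matrix Gaussian convolution with mirror (no edge repeat) padding
dense_smooth_oracle <- function(x, sigma) {
  n <- length(x)
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  reflect <- function(i) {
    # map an out-of-range index back into 1..n by mirror reflection
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in -half:half) {
      acc <- acc + kern[k + half + 1L] * x[reflect(i + k)]
    }
    out[i] <- acc
  }
  out
}

# brute-force peak scan: strict interior local maxima above the relative
# threshold, then greedy highest-first suppression of close pairs
brute_peaks_oracle <- function(x, min_sep, thr_rel) {
  n <- length(x)
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) return(integer(0))
  thr <- lo + thr_rel * (hi - lo)
  cand <- which(vapply(2:(n - 1L), function(i) {
    x[i] > x[i - 1L] && x[i] > x[i + 1L]
  }, TRUE)) + 1L
  cand <- cand[x[cand] >= thr]
  if (length(cand) <= 1L) return(as.integer(cand - 1L))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) > min_sep)) kept <- c(kept, p)
  }
  as.integer(sort(kept) - 1L)
}

# Kruskal-Wallis H from first principles (rank sums, tie correction)
kruskal_H_oracle <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, sum)^2 / tapply(r, groups, length)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# default synthetic movie used by the cross-module tests
make_default_movie <- function(sim_seed = 7L, detect_seed = 5L,
                               n_generations = 4L) {
  params <- sim_params(seed = sim_seed)
  sim <- simulate_lineage(params, n_generations)
  profiles <- render_profiles(sim)
  config <- pipeline_config(seed = detect_seed)
  list(sim = sim, profiles = profiles, config = config)
}

# match a pipeline focus position to the ground-truth focus id at a frame
truth_focus_id <- function(truth_foci, cell_id, frame, position_um,
                           radius = 0.15) {
  cand <- truth_foci[truth_foci$cell_id == cell_id &
                       truth_foci$frame == frame, ]
  if (nrow(cand) == 0L) return(NA_integer_)
  j <- which.min(abs(cand$position_um - position_um))
  if (abs(cand$position_um[j] - position_um) > radius) return(NA_integer_)
  cand$focus_id[j]
}

# a low-prominence shoulder bump riding a steep fluorescence gradient: it
# clears the relative threshold (its absolute intensity is high) but its
# prominence is well under half the trace sd
shoulder_trace <- function(bump_height = 10) {
  x <- 0:99
  peak <- 30 * exp(-(x - 20)^2 / 18)
  ramp <- ifelse(x >= 55, 44 * (1 - exp(-(x - 55) / 15)), 0)
  peak + ramp + bump_height * exp(-(x - 68)^2 / 2)
}
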