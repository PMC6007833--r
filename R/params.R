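#' Simulation parameters for the synthetic-lineage generator
#'
#' Defaults describe exponentially growing, asymmetrically dividing
#' rod-shaped cells imaged every 15 minutes, with a ParA intensity gradient
#' peaked near the new pole and ParB foci whose motion is sub-diffusive near
#' the ParA maximum and directed (toward the old pole) far from it.
#'
#' @param pixel_size length per pixel, um/px.
#' @param frame_interval imaging interval, h (0.25 h = 15 min).
#' @param elongation_rate exponential elongation rate, 1/h.
#' @param division_length length at which a cell divides, um.
#' @param division_asymmetry larger daughter's share of the parent length,
#'   in `[0.5, 1)`; jittered per division with a truncated Gaussian
#'   (sd 0.03) so sibling sizes vary.
#' @param parA_peak_frac position of the ParA maximum as a fraction of cell
#'   length measured from the new pole.
#' @param parA_peak_width Gaussian width (sd) of the ParA bump, um.
#' @param parA_amplitude,parA_baseline ParA bump height and baseline,
#'   intensity units.
#' @param spot_amplitude ParB spot height, intensity units.
#' @param spot_sigma Gaussian width (sd) of a rendered ParB spot, um.
#' @param noise_sd i.i.d. Gaussian pixel noise, intensity units.
#' @param near_regime_hurst Hurst exponent of the fractional-Gaussian-noise
#'   motion of foci near the ParA maximum, in `(0, 1)`; the resulting MSD
#'   exponent is `2 * near_regime_hurst`.
#' @param near_regime_step per-frame step scale of near-regime motion, um.
#' @param far_regime_speed directed speed of the focus segregating toward
#'   the old pole, um/h.
#' @param regime_switch_distance distance from the ParA maximum beyond which
#'   the old-pole-bound focus switches to directed motion, um.
#' @param seed integer seed for all randomness in the generator.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(pixel_size = 0.1,
                       frame_interval = 0.25,
                       elongation_rate = 0.23,
                       division_length = 5,
                       division_asymmetry = 0.57,
                       parA_peak_frac = 0.2,
                       parA_peak_width = 0.4,
                       parA_amplitude = 100,
                       parA_baseline = 20,
                       spot_amplitude = 100,
                       spot_sigma = 0.15,
                       noise_sd = 2,
                       near_regime_hurst = 0.2,
                       near_regime_step = 0.05,
                       far_regime_speed = 0.8,
                       regime_switch_distance = 0.8,
                       seed = 1L) {
  assert_scalar_num(pixel_size, "pixel_size", lower = 0, lower_open = TRUE)
  assert_scalar_num(frame_interval, "frame_interval", lower = 0, lower_open = TRUE)
  assert_scalar_num(elongation_rate, "elongation_rate", lower = 0)
  assert_scalar_num(division_length, "division_length", lower = 0, lower_open = TRUE)
  assert_scalar_num(division_asymmetry, "division_asymmetry",
                    lower = 0.5, upper = 1, upper_open = TRUE)
  assert_scalar_num(parA_peak_frac, "parA_peak_frac", lower = 0, upper = 1)
  assert_scalar_num(parA_peak_width, "parA_peak_width", lower = 0, lower_open = TRUE)
  assert_scalar_num(parA_amplitude, "parA_amplitude", lower = 0)
  assert_scalar_num(parA_baseline, "parA_baseline", lower = 0)
  assert_scalar_num(spot_amplitude, "spot_amplitude", lower = 0)
  assert_scalar_num(spot_sigma, "spot_sigma", lower = 0, lower_open = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(near_regime_hurst, "near_regime_hurst",
                    lower = 0, upper = 1, lower_open = TRUE, upper_open = TRUE)
  assert_scalar_num(near_regime_step, "near_regime_step", lower = 0)
  assert_scalar_num(far_regime_speed, "far_regime_speed", lower = 0)
  assert_scalar_num(regime_switch_distance, "regime_switch_distance", lower = 0)
  assert_scalar_num(seed, "seed", lower = 0, upper = 2^31 - 1)
  structure(
    list(
      pixel_size = pixel_size, frame_interval = frame_interval,
      elongation_rate = elongation_rate, division_length = division_length,
      division_asymmetry = division_asymmetry,
      parA_peak_frac = parA_peak_frac, parA_peak_width = parA_peak_width,
      parA_amplitude = parA_amplitude, parA_baseline = parA_baseline,
      spot_amplitude = spot_amplitude, spot_sigma = spot_sigma,
      noise_sd = noise_sd, near_regime_hurst = near_regime_hurst,
      near_regime_step = near_regime_step,
      far_regime_speed = far_regime_speed,
      regime_switch_distance = regime_switch_distance,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Pipeline configuration
#'
#' Aggregates every tunable of the analysis stages. Defaults are the
#' pipeline's canonical values: 2-px Gaussian smoothing, peaks separated by
#' more than 5 px and above 30% of the (baseline-subtracted) trace maximum,
#' 20 noise-perturbation trials with noise sd equal to half the trace sd
#' retaining peaks found in at least 10, a 5-px frame-to-frame link limit,
#' a 10-px split radius, a 0.15 um/h velocity threshold, MSD bin edges at
#' 0, 1.5, 3 and 4.5 um, and a 2.25-um minicell cutoff.
#'
#' @param pixel_size_um um per pixel.
#' @param frame_interval_h h between frames.
#' @param smoothing_sigma_px Gaussian smoothing sd, px.
#' @param peak_min_separation_px minimum peak separation, px.
#' @param peak_threshold_rel relative peak height threshold.
#' @param noise_trials number of noise-perturbation trials.
#' @param noise_retain_min minimum trials in which a peak must recur.
#' @param noise_sigma_factor perturbation sd as a fraction of the trace sd.
#' @param resmooth_sigma_px smoothing sd applied after perturbation, px.
#' @param match_radius_px radius for matching re-detected peaks to
#'   candidates, px.
#' @param link_max_px maximum frame-to-frame link displacement, px.
#' @param split_radius_px radius for automatic focus-split proposals, px.
#' @param velocity_threshold_um_h toward/with/away classification
#'   threshold, um/h.
#' @param msd_bin_edges_um initial-distance bin edges, um; series starting
#'   beyond the last edge are discarded.
#' @param msd_max_lag_frac largest lag used in the power-law fit, as a
#'   fraction of the longest series length.
#' @param minicell_max_um minicell length cutoff (inclusive), um.
#' @param seed integer seed for the stochastic stages.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(pixel_size_um = 0.1,
                            frame_interval_h = 0.25,
                            smoothing_sigma_px = 2,
                            peak_min_separation_px = 5,
                            peak_threshold_rel = 0.3,
                            noise_trials = 20,
                            noise_retain_min = 10,
                            noise_sigma_factor = 0.5,
                            resmooth_sigma_px = smoothing_sigma_px,
                            match_radius_px = 2,
                            link_max_px = 5,
                            split_radius_px = 10,
                            velocity_threshold_um_h = 0.15,
                            msd_bin_edges_um = c(0, 1.5, 3, 4.5),
                            msd_max_lag_frac = 0.5,
                            minicell_max_um = 2.25,
                            seed = 1L) {
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 0, lower_open = TRUE)
  assert_scalar_num(frame_interval_h, "frame_interval_h", lower = 0, lower_open = TRUE)
  assert_scalar_num(smoothing_sigma_px, "smoothing_sigma_px", lower = 0, lower_open = TRUE)
  assert_scalar_num(peak_min_separation_px, "peak_min_separation_px", lower = 1)
  assert_scalar_num(peak_threshold_rel, "peak_threshold_rel", lower = 0, upper = 1)
  assert_scalar_num(noise_trials, "noise_trials", lower = 1)
  assert_scalar_num(noise_retain_min, "noise_retain_min",
                    lower = 0, lower_open = TRUE, upper = noise_trials)
  assert_scalar_num(noise_sigma_factor, "noise_sigma_factor", lower = 0)
  assert_scalar_num(resmooth_sigma_px, "resmooth_sigma_px", lower = 0, lower_open = TRUE)
  assert_scalar_num(match_radius_px, "match_radius_px", lower = 0)
  assert_scalar_num(link_max_px, "link_max_px", lower = 0)
  assert_scalar_num(split_radius_px, "split_radius_px", lower = 0)
  assert_scalar_num(velocity_threshold_um_h, "velocity_threshold_um_h", lower = 0)
  if (!is.numeric(msd_bin_edges_um) || length(msd_bin_edges_um) < 2 ||
      is.unsorted(msd_bin_edges_um, strictly = TRUE)) {
    stop("'msd_bin_edges_um' must be a strictly increasing numeric vector",
         call. = FALSE)
  }
  assert_scalar_num(msd_max_lag_frac, "msd_max_lag_frac",
                    lower = 0, upper = 1, lower_open = TRUE)
  assert_scalar_num(minicell_max_um, "minicell_max_um", lower = 0, lower_open = TRUE)
  assert_scalar_num(seed, "seed", lower = 0, upper = 2^31 - 1)
  structure(
    list(
      pixel_size_um = pixel_size_um, frame_interval_h = frame_interval_h,
      smoothing_sigma_px = smoothing_sigma_px,
      peak_min_separation_px = as.integer(peak_min_separation_px),
      peak_threshold_rel = peak_threshold_rel,
      noise_trials = as.integer(noise_trials),
      noise_retain_min = as.integer(noise_retain_min),
      noise_sigma_factor = noise_sigma_factor,
      resmooth_sigma_px = resmooth_sigma_px,
      match_radius_px = match_radius_px,
      link_max_px = link_max_px,
      split_radius_px = split_radius_px,
      velocity_threshold_um_h = velocity_threshold_um_h,
      msd_bin_edges_um = msd_bin_edges_um,
      msd_max_lag_frac = msd_max_lag_frac,
      minicell_max_um = minicell_max_um,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}
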