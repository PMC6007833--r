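# parabtrack

Single-cell analysis of ParA/ParB chromosome-partitioning dynamics in
time-lapse fluorescence movies of rod-shaped bacteria (built around the
*Mycobacterium smegmatis* ParABS system).

In these movies ParB marks origin-proximal *parS* sites as discrete
fluorescent foci that duplicate and segregate, while ParA forms an
intracellular gradient whose maximum sits near the new cell pole. The
package is for microscopists and quantitative biologists who already have
per-cell **axial fluorescence profiles** (1-D intensity along the cell's
long axis, two channels) plus a **cell table** (frame, cell id, parent id,
length, pole identity) from a segmentation tool, and want the downstream
numbers:

- ParB focus detection on smoothed profiles with a 20-trial
  noise-perturbation validation (peaks kept only if re-found in ≥10 of 20
  noise-injected re-detections);
- focus tracking across frames and cell divisions (greedy
  nearest-neighbour, 5-px step limit, pole-relative coordinates), with
  automatic focus-split proposals and a plain-text manual-override file;
- mean-squared-displacement analysis of each focus's distance to the ParA
  maximum, binned by initial distance (0–1.5, 1.5–3, 3–4.5 µm) and fitted
  to the anomalous-diffusion law **⟨Δx²⟩ = 2D·(Δt)^β** (β < 1
  sub-diffusive, β = 1 free, β > 1 active transport);
- velocity classification of each focus as moving *toward*, *with*, or
  *away from* the ParA maximum (±0.15 µm/h slope threshold);
- sibling-cell ParA inheritance: totals, maxima, who inherits the
  parent's ParA maximum, and the size-ratio null prediction for random
  inheritance (expected count = Σ larger-daughter size share);
- lineage statistics (log-linear growth rates, doubling times, minicell
  calls at ≤2.25 µm) and rank-based group comparisons (paired
  Wilcoxon + Welch; Kruskal–Wallis with Dunn's post-hoc letter classes).

A ground-truthed synthetic-lineage simulator (exponential growth,
asymmetric division, fractional-Gaussian-noise focus motion near the ParA
maximum, directed motion toward the old pole far from it) generates the
movies every stage is tested against, so the package needs no bundled
microscopy data.

## Worked example

```r
library(parabtrack)

params   <- sim_params(seed = 7)                 # study-condition defaults
sim      <- simulate_lineage(params, n_generations = 4)
profiles <- render_profiles(sim)
res      <- run_pipeline(sim$cells, profiles, pipeline_config(seed = 5))
res$fits
```

```
      bin         D      beta        se_D    se_beta       regime n_lags
1 [0,1.5) 0.2077592 1.0313717 0.009170311 0.04558112         free     17
2 [1.5,3) 0.2350698 0.5356429 0.021200837 0.07653689 subdiffusive     23
3 [3,4.5)        NA        NA          NA         NA         <NA>      0
```

Foci that start within 1.5 µm of the ParA maximum show β ≈ 1 here (their
fGn motion is overlaid by growth advection of the landmark), the middle
bin is clearly sub-diffusive, and the far bin collects no series on this
small movie. The same bundle carries the rest of the analysis:

```r
res$inheritance_prediction[c("n_divisions", "expected_larger_count",
                             "observed_larger_count")]
#> $n_divisions            [1] 7
#> $expected_larger_count  [1] 4.066674
#> $observed_larger_count  [1] 2
```

The numbered drivers under `analysis/` run the full workflow on a fresh
simulation and print recovery diagnostics against the generator's ground
truth; on the default movie (`Rscript analysis/01_simulate.R` … `05`):

```
detection: 395 foci found; 98.0% of 397 true foci recovered within 1 px
tracking: 23 tracks, 5 split proposals (15 true splits)
calibration brownian: beta = 0.995 (free)
calibration subdiffusive: beta = 0.397 (subdiffusive)
calibration ballistic: beta = 2.000 (active)
uniform-placement null, 10000 simulated divisions: observed/expected = 1.019
```

Kymographs (lifetime-normalised ParA heatmap, black = min, white = max,
new pole at the bottom, ParB tracks overlaid) land in
`results/kymographs/`.

## Input and output schemas

- **Cell table** (CSV): `frame`, `time_h`, `cell_id`, `parent_id`
  (empty for roots), `length_um`, `new_pole_end` ∈ {left, right,
  unknown}.
- **Profile table** (CSV, long): `cell_id`, `frame`, `pixel_index`
  (0-based), `parA_intensity`, `parB_intensity`. Pixels run along the lab
  axis; positions are reported in µm from the new pole (left pole when
  unknown).
- **Foci** CSV: `cell_id`, `frame`, `position_px`, `position_um`,
  `intensity`, `validation_count`. **Tracks** CSV adds `track_id`.
- **Override file** (one command per line, `#` comments allowed):
  `merge A B` appends track B onto A; `split_link P C1 C2` declares C1,
  C2 children of P; `split_unlink P` removes P's split record. Dangling
  ids and frame collisions are hard errors.
- **MSD** CSV: `bin`, `dt_h`, `msd_um2`, `ci_low`, `ci_high`, `n_pairs`;
  fits and summary statistics as JSON.

All thresholds (smoothing σ = 2 px, separation 5 px, 10-of-20 retention,
noise factor 0.5, link 5 px, split radius 10 px, velocity 0.15 µm/h, MSD
bin edges, minicell 2.25 µm) live in `pipeline_config()`.

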