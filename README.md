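# smlmtools

An R toolkit for analysing single-molecule localization microscopy (SMLM)
data — PALM, dSTORM and DNA-PAINT experiments in which individually
blinking fluorophores are localized with sub-pixel precision and the
resulting coordinate lists are assembled into super-resolved images or
single-particle statistics. It is aimed at microscopists and image
analysts who want a scriptable, testable pipeline covering every step
from the raw camera movie to quantitative readouts, plus a seeded
simulator that provides ground truth for validating each step.

## What it does

**Pre-processing and localization**

- *Temporal median background subtraction*: for each pixel at time *t* the
  median over a window of *i* frames (default 51) is subtracted; because
  blinking equilibria favour the off-state, this median tracks the slowly
  varying background. Near the movie ends the window is shifted, never
  shrunk.
- *Spot detection and phasor localization*: difference-of-Gaussian
  filtering highlights PSF-sized blobs; candidates above a robust
  threshold (median + k·1.4826·MAD) that are local maxima of the raw
  frame are cut out as 7×7 ROIs and localized by the phase angles of the
  first-order Fourier coefficients — a non-iterative estimator whose
  precision scales as 1/√N with photon count N.

**Post-processing**

- *Merging* (`link_localizations` + `merge_linked`): re-detections of one
  emission burst across consecutive (or gap-separated) frames are fused
  into a single event with intensity-weighted mean position
  x̄ = Σxᵢ Nᵢ / ΣNᵢ, minimum frame, summed intensity.
- *Drift correction*: from fiducial-marker tracks (averaged per-frame
  displacement traces) or, for static structures, from the spectral
  cross-correlation of temporally binned sub-pixel renderings.
- *Chromatic correction*: least-squares 2D affine transform
  (x,y) → (a·x+b·y+t_x, c·x+d·y+t_y) estimated from paired control points.

**Data interpretation**

- *Rendering*: 2D histogram, bilinear, or per-localization Gaussian
  rasters at a configurable zoom (sub-pixels per camera pixel).
- *Tracking statistics*: jump-distance (JD) histograms fitted with
  Rayleigh mixtures p(r) = Σ fᵢ · r/(2Dᵢτ) · exp(−r²/4Dᵢτ), per-track mean
  jump distances (mJD) fitted with Gaussian mixtures, and ensemble MSD
  curves fitted as MSD = 4DΔt + 4σ².
- *Clustering*: deterministic DBSCAN with core/edge/noise roles.
- *Resolution and precision*: Fourier ring correlation (resolution at the
  1/7 threshold crossing) and NeNA (localization precision from
  adjacent-frame nearest-neighbour distances fitted with
  p(d) = d/(2σ²)·exp(−d²/4σ²)).

**Simulation** (`simulate_movie`, `simulate_tracks`,
`simulate_nanoruler_pairs`, `simulate_static_locs`, `simulate_drift`):
blinking emitters with two-state Markov kinetics, pixel-integrated
Gaussian PSFs, Poisson + read noise, inhomogeneous background, lateral
drift, fiducials, Brownian mixtures and two-colour bead scenes — all pure
functions of (parameters, seed), with full ground truth returned.

## Worked example

```r
library(smlmtools)

# simulate a 300-frame movie of 15 blinking emitters on a sloped background
set.seed(42)
pos <- cbind(runif(15, 6, 42), runif(15, 6, 42))
sim <- simulate_movie(
  emitter_model(pos, k_on = 0.05, k_off = 0.5, photons_per_frame = 3000),
  noise_model(background_offset = 20, background_gradient = c(0.1, 0.05),
              read_noise_sigma = 2),
  n_frames = 300, shape = c(48, 48), seed = 42)
sim$movie
#> smlm_movie: 300 frame(s) of 48 x 48 px, 100.0 nm/px, 0.03 s/frame

# background subtraction, detection, phasor localization
filtered <- temporal_median_filter(sim$movie, window_frames = 51)
locs <- localize_movie(sim$movie, filtered, detection_params(threshold_k = 6))
locs
#> loc_table: 426 localization(s), 100 nm/px

# localization precision from adjacent-frame nearest neighbours
nena_precision(locs)
#> nena_fit: sigma = 0.03901 px (3.90 nm) from 213 distances

# merge per-burst re-detections, then render
linked <- link_localizations(locs, link_params(max_jump_px = 0.8,
                                               max_gap_frames = 2))
merged <- merge_linked(linked)
nrow(merged)
#> [1] 209
render_gaussian(merged, zoom = 10, sigma_render_px = 0.039 * 10)
#> rendered_image: 360 x 380 render px, zoom 10, origin (3, 7), sum 207.049
```

The 426 raw localizations are re-detections of 15 emitters over ~209
emission bursts; NeNA reports a per-axis precision of 3.9 nm, consistent
with ~3000 detected photons per frame on a modest background. The
detection threshold `threshold_k` trades recall against false positives —
on sparse scenes like this one, raising it from the default 3 to 6
removes essentially all noise detections at no cost in true ones.

A command-line front end over the same functions is installed at
`inst/scripts/smlm.R`
(`Rscript inst/scripts/smlm.R localize --threshold 6 in.tif out.csv`, and
analogous subcommands for every stage), and `run_pipeline()` chains
stages from a single config with a JSON run manifest.

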