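---
title: "Models and methods behind smlmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smlmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `smlmtools`, the
assumptions behind them, the parameters that matter, and the design
choices made where the methodology left them open. It states no
empirical result beyond what the package's tests and
`scripts/acceptance.R` compute themselves.

## Coordinate conventions

All positions are in camera-pixel units. Pixel `(row i, col j)`
(0-based) covers the half-open square `[j, j+1) × [i, i+1)` in `(x, y)`,
so the centre of pixel `(0,0)` is `(0.5, 0.5)`; `x` runs along columns,
`y` along rows, and frames are 0-based. This single convention is used
by the simulator, the localizer (`x = col_peak + 0.5 + dx`), all
renderers (render-bin centre of bin `(r, c)` at
`(xmin + (c+0.5)/zoom, ymin + (r+0.5)/zoom)`) and the estimators, which
removes the classic half-pixel ambiguity between localization and
visualisation. Some exporters (e.g. RapidSTORM-style tables) put the
pixel-(0,0) centre at `(0, 0)`; the reader's `dialect$shift_px = 0.5`
compensates. Conversions to nm multiply by `pixel_size_nm`.

## Temporal median background subtraction

For pixel trace `v` and frame `t`, the filter output is
`v[t] − median(v[w(t)])` where `w(t)` is a window of `i` frames centred
on `t`. Because SMLM blinking equilibria favour the off-state, the
windowed median estimates the (slowly varying) background rather than
signal. Choices:

* **Window shifted, never shrunk, at the movie ends.** The first and
  last `⌊i/2⌋` frames use the window anchored at the movie boundary, so
  the statistic always pools exactly `i` samples and its breakdown point
  is constant.
* **`i` must be odd** (unambiguous middle order statistic) and defaults
  to 51 frames — comfortably more than twice a typical on-period. The
  filter is inappropriate when emitters are on more than ~half the
  time; the package does not try to auto-detect this (it cannot, without
  knowing the blinking kinetics), it is the caller's responsibility.
* **Negative residuals are clamped at 0 by default** (`clamp = FALSE`
  keeps signed output). Clamping is a convenience for TIFF export and
  visual inspection; the downstream detector tolerates signed input.

## Detection and phasor localization

Detection runs on the (filtered) movie: a difference-of-Gaussian
bandpass (defaults σ = 1.0 and 2.0 px, bracketing a diffraction-limited
PSF of σ ≈ 1.3 px at 100 nm pixels) followed by a robust threshold,
`median + k · 1.4826 · MAD` of the DoG frame. The MAD-based scale is
insensitive to the bright-emitter tail; the default `k = 3` favours
recall, and sparse scenes benefit from `k = 5–6` (the README example
quantifies this trade-off on simulated truth). Candidates must also be
local maxima of the *raw* frame (plateau ties resolved to the smallest
(row, col)), at least one ROI away from the border; candidate pairs
closer than `2·roi_halfsize` are both dropped because the fit assumes
one emitter per ROI.

Sub-pixel localization uses the phasor method: with ROI side `N = 2h+1`,
the first-order DFT coefficients along each axis,
`Fx = Σ roi[v,u]·exp(−2πi·u/N)` (and `Fy` with `v`), encode the position
of a concentrated intensity distribution in their phase. The phase is
mapped so that a delta at integer pixel `(u0, v0)` returns exactly
`(u0−h, v0−h)` and a centred symmetric PSF returns `(0, 0)`; these two
anchor cases fix the sign/orientation convention, which published phasor
variants differ on. ROIs are cut from the *raw* movie with the ROI
minimum subtracted as local background; `intensity` is the
background-subtracted ROI sum. A constant ROI (both first-order
magnitudes < 1e−12) is rejected as degenerate. An iterative
least-squares Gaussian fit exists in the test suite as an oracle only —
the production path is deliberately non-iterative.

## Linking, merging and tracking

One linker serves both merging and tracking. Frames are processed in
order; each open trajectory head is matched to its nearest unclaimed
localization within `max_jump_px`, trying gap 0 first and only falling
back to longer gaps (up to `max_gap_frames`) for heads unmatched at
shorter ones. Within a frame pair, assignments are resolved **globally
greedily in ascending distance** (ties to the lower row index). A naive
per-localization loop depends on input order; the global greedy rule is
deterministic and order-free, which is the package's stated resolution
of a conflict the loop formulation leaves open. Track ids are
consecutive integers in order of track start.

Merging collapses each track to the intensity-weighted mean position,
minimum frame and summed intensity — total intensity is conserved
exactly, and the merged position's precision improves roughly as the
square root of the number of fused detections. Fiducial tracks are
passed through via `exclude_ids`. At high density, a diagnostic warning
fires when more than 5% of merged tracks have mean internal steps above
`max_jump_px/2`, the signature of fusing different fluorophores.

## Drift correction

**Fiducial route.** Tracks spanning at least `min_presence_fraction`
(default 0.9) of the movie are classified as fiducials. Each marker's
displacement is taken **relative to its own first observation** — not a
global frame — so markers first detected late do not bias the trace;
traces are averaged across markers, gaps filled by linear interpolation,
optionally smoothed by a centred moving average, and the result
re-zeroed at frame 0. Averaging m markers with independent errors
reduces the trace noise by √m (a property the tests verify at m = 3).

**Cross-correlation route** (static structures only). Frames are
partitioned into bins of `bin_frames`, each bin rendered as a 2D
histogram at `zoom` sub-pixels per camera pixel, and the shift of bin k
against bin 0 read from the peak of their spectral cross-correlation,
refined per axis by a three-point parabola. Shifts are attributed to bin
temporal centres and interpolated to per-frame resolution with a natural
cubic spline, held flat beyond the outer centres, re-zeroed at frame 0.
Numerical notes:

* The correlation is circular (no zero-padding); this is exact for pure
  integer-render-pixel shifts and adequate for drifts that are small
  fractions of the field, which is the method's domain of validity
  anyway. A warning fires if a recovered shift exceeds a quarter of the
  field.
* **Bin width is the accuracy-limiting parameter.** Two error terms grow
  with bin width: drift within a bin blurs the rendered structure and
  biases the per-bin shift toward the bin average, and the offset
  between frame 0 and the bin-0 centre is unobservable by construction.
  Both shrink with narrower bins, until too few localizations per bin
  make the correlation peak noisy. Choose bins so the expected drift
  within one bin stays below the localization precision while keeping
  at least ~1000 localizations per bin; the acceptance script uses
  25-frame bins (~1800 locs/bin) under its drift speed. The default
  `n_frames/10` is a coarse starting point for slower drift.
* Strictly periodic structures (e.g. a perfect bead grid) make the
  cross-correlation shift ambiguous modulo the lattice constant and
  must be avoided; validation scenes are aperiodic for this reason.

`apply_drift` subtracts the trace from all localizations; both
estimators return exactly (0,0) at the reference frame.

## Chromatic correction

The moving channel is mapped onto the reference by a full 6-parameter
affine transform estimated by least squares from paired control points
(≥ 3, non-collinear; condition number checked against 1e8). A
translation-only mode covers dual-view registration. Pairs come from an
explicit CSV (`x_ref,y_ref,x_mov,y_mov`) or from the mutual
nearest-neighbour pairing helper, replacing manual pair picking.
Correction is applied to localizations, not rendered images, so
downstream quantification stays on the coordinate list.

## Rendering

Histogram and bilinear renderers conserve total weight exactly; the
Gaussian renderer normalises each kernel analytically and truncates at
4σ, keeping the total within 1%. The Gaussian mode convolves the
localization scatter (width σ_loc) with the render kernel (width
σ_render), so the apparent width is √(σ_loc² + σ_render²) — setting
σ_render = σ_loc costs a factor √2 in apparent resolution, which the
acceptance script measures directly. Default zoom is 10 sub-pixels per
camera pixel; much finer zoom than the localization precision suggests
detail that is not there. Scatter plots are intentionally not part of
the library core.

## Diffusion analysis

Single-frame jump distances of 2D Brownian motion follow a Rayleigh
(noncentral chi) law; a k-state mixture has density
`p(r) = Σ fᵢ · r/(2Dᵢτ) · exp(−r²/4Dᵢτ)`. The production fit is least
squares against the normalised histogram (initialised from quantiles of
`r²/4τ`), because histogram fitting is the field's customary procedure —
but the bin count can matter, so the fit is automatically repeated at
half and double `n_bins` and flagged when any D moves more than 10%, and
a bin-free maximum-likelihood fit on the raw distances is available as a
cross-check (`method = "mle"`). Localization error is *not* subtracted:
the fitted values are apparent coefficients D*.

Per-track mean jump distances (mJD) of long tracks are approximately
Gaussian by the central limit theorem and separate similar populations
more cleanly than the pooled histogram; Gaussian means are converted via
`E[r] = √(πDτ)`, which assumes pure 2D Brownian motion (the method has
no general conversion; this assumption is the package's documented
choice). The ensemble MSD pools squared displacements over all tracks
and start positions and fits `MSD = 4DΔt + 4σ²` by weighted least
squares over the first 4 lags only — long-lag points of short tracks are
noise-dominated — reporting D, the intercept-implied σ (clamped at 0),
and their standard errors.

## DBSCAN

A point is *core* when at least `min_points` localizations (including
itself — the standard convention, switchable with `count_self`) lie
within ε; *edge* when non-core but within ε of a core; *noise*
otherwise. Clusters are connected components of the core–core graph,
expanded by an iterative worklist (output-identical to the textbook
recursion, immune to stack limits). Determinism is imposed where classic
DBSCAN is order-dependent: components are numbered by smallest contained
row index, and an edge point adjacent to several clusters joins the
lowest-labeled one — so row permutations change labels only through this
documented rule, never the core/edge/noise partition. Distances are in
px or, with `units = "nm"`, scaled by the table's pixel size. The
implementation is brute-force O(n²) on the distance matrix, appropriate
for the ≤ 10⁴-point fields it targets.

## Resolution (FRC) and precision (NeNA)

**FRC.** The table is split uniformly at random (seeded) — an odd/even
frame split would correlate re-detections of the same emitters across
the halves and overestimate resolution. Both halves are rendered as
histograms on a common square, zero-padded to a `nextn` side with at
least a 16-bin margin; rings are integer-rounded radial frequency
indices; the curve is smoothed with a centred 7-ring moving average and
the resolution read at the first downward 1/7 crossing, linearly
interpolated, as `1/q` with `q = ring/(N·render_pixel_nm)`. Ring 0 is
exactly 1 for any non-empty pair. If the curve never crosses before
Nyquist the result is `NA` with the curve returned. Note that the two
halves share the field envelope (the window edges), which genuinely
correlates low rings even for structure-free data — decorrelation claims
only hold beyond the envelope's support. The render pixel (default
10 nm, 5 nm used in the validation scenes) should sit well below the
expected resolution.

**NeNA.** In non-merged static data, the nearest neighbour in the next
frame is usually the same emitter re-localized, so the true distance is
zero and the measured distance follows `p(d) = d/(2σ²)·exp(−d²/4σ²)`
with σ the per-axis precision (each coordinate difference has variance
2σ²). Distances beyond a capture radius (default 2 px) are discarded as
unrelated emitters; the density is fitted to the histogram by least
squares. The estimator fails by design on merged data, on emitters that
live ≪ 1 frame, and degenerates (with an explicit error) when all
distances are zero. An intensity threshold optionally splits the table
(e.g. fiducials vs signal) into separately fitted classes. The original
method's background-correction terms are not implemented.

## The simulator: what it does and does not emulate

`simulate_movie` draws blinking states from a two-state Markov chain per
frame (initialised at stationarity, long-run on-fraction
`k_on/(k_on+k_off)`), integrates the Gaussian PSF over pixel edges via
CDF differences (point sampling would alias exactly the sub-pixel
structure the phasor tests probe), adds a planar, slowly creeping
background, applies Poisson shot noise to signal + background and adds
Gaussian read noise. Fiducials are the `k_on = 1, k_off = 0` special
case. `simulate_tracks` draws per-axis increments with variance 2Dτ;
`simulate_static_locs` shortcuts image formation for post-processing
tests; `simulate_drift` builds smooth traces from slow sinusoids plus a
linear term. Everything is a pure function of (parameters, seed).

Deliberately **not** modelled: EMCCD excess noise and sCMOS per-pixel
noise maps, triplet/sub-frame photophysics, aberrated or 3D PSFs,
axial drift, and structured (non-planar) background. Tests passing on
this simulator therefore validate the algorithms' correctness and
calibration under idealised camera statistics — not robustness to every
real-camera artefact.

## Study conditions used by tests and the acceptance script

Chosen once as realistic for the emulated experiments: 100 nm pixels,
PSF σ 1.3 px, 2000-frame drift acquisitions with 50–80 nm smooth drift,
fiducial precision 5 nm, structural scenes at 10 nm precision with
10⁵ localizations, diffusion mixtures at D = 0.05–1 px²/frame with
10⁴–2·10⁴ jumps, photon series N ∈ {250, 1000, 4000, 16000} at
background 1 count/px — the shot-noise-limited regime in which the
1/√N precision law is the prediction; at high background the low-N end
becomes background-dominated and the log-log slope steepens. Problem
sizes (300-frame localization movies, 48–50 px fields) keep the whole
validation suite at desktop scale while leaving every estimator well
inside its asymptotic regime.

## Known limitations

Single-emitter fitting only (no multi-emitter/high-density mode); basic
pairwise cross-correlation (no redundant all-pairs variant); nearest-
neighbour tracking can mislink crossing trajectories — its known failure
modes (no trajectory termination rule, radius truncation) are inherited
by design; DBSCAN results degrade when cluster anisotropy matches the
search radius; FRC applies only to tables of static structures; the mJD
→ D conversion assumes free diffusion. The CLI is a thin convenience
layer; the R API is the primary interface.
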