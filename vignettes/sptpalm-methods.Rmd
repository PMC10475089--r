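---
title: "Methods: sptPALM analysis of membrane-protein mobility in rod-shaped bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sptPALM analysis of membrane-protein mobility in rod-shaped bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptpalm)
```

## The measurement problem

Single-particle-tracking PALM (sptPALM) follows individual
photoactivatable fluorescent fusion proteins in the membrane of living
bacteria. A 405 nm pulse switches on a sparse, random subset of
molecules; a second laser images them at video rate (here 10 Hz with a
160 nm effective pixel) until they photobleach. Each molecule yields a
short trajectory, and the population of trajectories answers two
questions about a membrane enzyme such as a peptidoglycan synthase or
hydrolase:

1. **How mobile is it?** Enzymes bound to the (essentially stationary)
   peptidoglycan meshwork appear immobile; unengaged enzymes diffuse in
   the membrane with coefficients of order $10^{-2}\,\mu m^2/s$.
2. **Where is it?** On a rod-shaped cell, the fraction of particles at
   the cell poles, compared against the fraction of *surface area* the
   poles contain, measures polar enrichment.

This package implements the full chain — spot detection, sub-pixel
fitting, trajectory linking, mobility classification, anomalous-exponent
and diffusion-coefficient estimation, pole assignment, and bootstrap
population statistics — together with a ground-truthed simulator so that
every stage can be validated quantitatively without microscope data.

## Models and estimators

### Localization

Candidate spots are local maxima of a difference-of-Gaussians filter
($\sigma_1 = 1$, $\sigma_2 = 3$ pixels) exceeding `detection_threshold`
(default 5) times the robust (MAD) SD of the filtered frame; maxima
closer than one fit window are merged to the brighter one. Each
candidate is fitted by nonlinear least squares with a symmetric 2D
Gaussian *integrated over each pixel*,

$$\mu_{ij} = b + N\,
 \left[\Phi\!\left(\tfrac{x_j - x_0 + p/2}{\sigma}\right) -
       \Phi\!\left(\tfrac{x_j - x_0 - p/2}{\sigma}\right)\right]
 \left[\text{same in } y\right],$$

with $p$ the pixel size. At $p = 160$ nm and PSF
$\sigma \approx 130$ nm the pixel integral matters; a point-sampled
Gaussian would misestimate $\sigma$ and, off-center, the position. The
pixel in 0-based row $i$, column $j$ has center
$((j+0.5)p,\,(i+0.5)p)$; this convention is used identically by the
renderer and the fitter, and the round trip recovers positions to a few
nanometres at high signal. Fits are rejected when $\sigma$ leaves
$[0.3, 3]$ pixels, the optimizer fails, or the center leaves the
window; candidates within half a window of the frame edge are skipped
and logged.

### Linking and retention

Localizations in consecutive frames are linked by a globally optimal
one-to-one assignment (Hungarian algorithm) restricted to pairs within
`max_link_distance` = 320 nm (two pixels); unmatched spots open or
close tracks and there is no gap closing — a blink ends the track.
Global assignment, unlike greedy nearest-neighbour, is deterministic
and correct on crowded frames; a brute-force enumeration oracle
verifies it in the test suite. Only tracks lasting 4–12 frames
(0.4–1.2 s at 10 Hz, counting $n$ frames as $n \times 0.1$ s) are
retained: shorter tracks carry too little information, longer ones are
rare and dominated by aggregates; over-long tracks are rejected whole,
never truncated, which would manufacture data.

### Mobility, $\alpha$, and $D$

A retained track is **immobile** when the axis-aligned bounding box of
its positions is smaller than one pixel (both sides $< 160$ nm) —
the particle never explored more than a pixel before bleaching.
For mobile tracks the time-averaged mean squared displacement

$$\mathrm{TAMSD}(k\,\Delta t) = \frac{1}{n-k}\sum_{i=1}^{n-k}
 \left[(x_{i+k}-x_i)^2 + (y_{i+k}-y_i)^2\right]$$

is computed for all lags, and two fits are made on the first four lags:

* $\log \mathrm{TAMSD} = \log(4D) + \alpha \log \Delta t$ — the
  anomalous exponent $\alpha$ ($\alpha = 1$ free diffusion, $<1$
  subdiffusion, $2$ ballistic). Mobile tracks are retained only for
  $0 \le \alpha \le 1.5$, the range characteristic of diffusive
  membrane particles in this regime; both bounds are inclusive so the
  retained count is reproducible.
* $\mathrm{TAMSD} = 4D\,\Delta t + c$ — the diffusion coefficient from
  the slope. The intercept $c$ is left free because static
  localization error adds $4\sigma_{loc}^2$ to every lag; forcing the
  line through the origin (available via `through_origin = TRUE`)
  would bias $D$ upward by roughly $\sigma_{loc}^2/\Delta t$. Tracks
  with non-positive fitted $D$ are flagged but kept in the population
  mean, since no principled exclusion rule exists for them.

Both fits need four lags, i.e. five frames. Four-frame tracks are
classified but carry no $\alpha$ or $D$ (cause `too_few_lags`); they
still count in the immobile-fraction denominator. A pooled
ensemble-MSD fit (`ensemble_msd_fit()`) is provided as a cross-check
on the per-track mean.

### Spatial statistics

The pole of a rod is defined as the surface within 480 nm (three
pixels) of a cell end, measured as arc length along the cell's
centerline — on a straight cell this equals the axial distance, and on
a curved cell the axis is the only meaningful ruler. For an idealized
spherocylinder (cylinder length $L - W$, radius $r = W/2$) the pole
zone of depth $d \le r$ is a spherical zone of area $2\pi r d$
(Archimedes), giving

$$f_{pole} = \frac{2 \cdot 2\pi r d}{2\pi r (L - W) + 4\pi r^2},$$

which evaluates to 0.192 for $L = 5\,\mu m$, $W = 1\,\mu m$,
$d = 480$ nm — the benchmark that uniform surface-random particles
must reproduce, and the null against which polar enrichment is judged.
A particle (track) is assigned by its first localization; tracks
almost never cross the 480 nm boundary within 1.2 s, and a
majority-vote option exists.

Cell morphometry from binary masks: the centerline is the smoothed
transverse mid-line along the principal axis, extended to the outline
at both tips; length is its arc length; width is twice the
near-maximal (95th percentile) distance-transform value along the
central half of the centerline. The percentile, rather than the
median, is deliberate: along a rod's axis the distance transform is
flat so the two coincide, but for near-isotropic shapes (sporulating
cells rounding up) the transform tapers away from its single central
peak and the median would understate the width by up to a third,
breaking the $L/W \to 1$ limit that makes the ratio a useful
sporulation index.

### Population statistics

Per-condition summaries report the immobile fraction over all retained
tracks and the mean $D$ over mobile, $\alpha$-retained tracks. Both
uncertainties come from 1000 bootstrap resamples of whole tracks —
never of individual displacements, which are correlated within a
track. Two condition means are called significantly different when
they differ by more than 0.005 in native units ($\mu m^2/s$ for $D$,
dimensionless for fractions); the rule is symmetric and
self-comparison is never significant. A classical one-way ANOVA
(`one_way_anova()`, a thin wrapper over `lm`/`anova`) is included for
cell-dimension comparisons.

## The simulator: what it emulates, and what not

`simulate_tracks()` places particles uniformly on a spherocylindrical
surface lying on the coverslip, assigns each a permanent state
(immobile with probability `frac_immobile`; state switching is omitted
because tracks last at most 1.2 s), and activates them at a Poisson
rate per frame until the pool is exhausted. Fluorescent on-times are
geometric with mean `mean_on_frames` (default 8, centering the
4–12-frame window). Mobile particles take Euler steps in the local
tangent plane with per-axis variance $2D\,\Delta t$ followed by
orthogonal reprojection to the surface — standard and convergent for
$D\,\Delta t \ll r^2$ (here $D\,\Delta t / r^2 \approx 0.01$). HILO
illumination is modelled as a hard visibility slab: a particle is
observed only when its height above the coverslip is at most
`hilo_depth` (default 300 nm); a soft axial intensity profile would
add parameters without a testable benefit. Observed positions are the
planar projections plus isotropic Gaussian noise of SD
`localization_sigma` (default 20 nm). `render_movie()` turns observed
positions into 16-bit camera frames using the same integrated-Gaussian
PSF as the fitter plus Poisson shot noise on signal and background.

Deliberately not modelled: EMCCD gain and read noise, astigmatic 3D
PSFs, TIRF-style exponential intensity decay, molecular state
switching, and drift. Consequently, passing tests demonstrate the
correctness and calibration of the *analysis* under idealized imaging,
not robustness to every camera artifact of real data.

Defaults (`simulation_config()`): $D = 0.0272\,\mu m^2/s$ and
immobile fraction 0.131 — representative values for a peptidoglycan
hydrolase in untreated cells — on a $5 \times 1\,\mu m$ cell at 10 Hz.
The HILO depth and localization precision of a real instrument are not
knowable from first principles; 300 nm and 20 nm are realistic
free parameters of the simulator, chosen once.

## Known estimator limitations (measured by the validation suite)

Three biases are inherent to the method at these conditions, and the
test suite measures rather than hides them:

* **Short-track misclassification.** With step SD
  $\sqrt{2D\Delta t} \approx 74$ nm, a genuinely mobile particle seen
  for only 4 frames stays inside a 160 nm box almost half the time;
  across the geometric 4–12-frame mix the false-immobile rate is
  ≈ 0.15 (the suite verifies the pipeline against an independent
  Monte-Carlo of the bounding-box statistic to ±0.03). Raw immobile
  fractions are therefore upward-biased by roughly
  $(1-f) \times 0.15$; comparisons *between* conditions sharing a
  length distribution remain valid, which is how such fractions are
  used.
* **Log-domain $\alpha$ bias.** The few-pair TAMSD values at lags 3–4
  are noisy, and the log transform converts their scatter into a
  downward bias of the fitted exponent: the median $\alpha$ of free
  Brownian tracks at these conditions is ≈ 0.84 with 20 nm noise
  (≈ 0.92 without). $\alpha$ is used here only as a retention filter,
  for which this bias is immaterial.
* **Surface-projection compression.** The camera sees the planar
  projection of motion on a curved surface; within a 300 nm HILO slab
  the transverse coordinate is compressed by the local $\cos\varphi$,
  depressing apparent $D$ by ∼10–15%. The free-diffusion estimator
  itself is unbiased: the suite separates the two effects by
  validating estimators on planar tracks and the end-to-end chain on
  surface tracks with a correspondingly wider tolerance.

## Numerical and reproducibility choices

* All tables are CSV with doubles serialized as `%.17g`, so
  write–read round trips are bit exact; movies are uncompressed 16-bit
  multi-page TIFF.
* One master seed fans out to fixed per-stage seeds
  (`simulate`, `render`, `summarize`, …), so any stage can be rerun
  alone and the end-to-end demo is byte-reproducible; the run manifest
  records the configuration, seed, and the counts entering and leaving
  every filter.
* Ties in the linking assignment are broken by the deterministic input
  ordering (frame, then position); distances exactly at the 320 nm
  gate are linked (inclusive), as are $\alpha$ values exactly at 0 or
  1.5 and tracks of exactly 4 or 12 frames.
* Degenerate inputs: empty frames and empty tables propagate as empty
  results; an all-zero fit window, a fragmented or sub-20-pixel mask,
  a zero-valued TAMSD entry inside the fit range, and a localization
  outside all masks each fail loudly with a named cause rather than
  silently.

## Problem sizes used in validation

The suite validates estimator calibration at 2000 tracks per
condition, the geometry linchpin (surface sampling vs closed form) at
$10^5$–$10^6$ points, the TAMSD identity on 1000 random tracks against
an $O(n^2)$ reference, localization accuracy over 40–100 rendered
spots per photon level, and the end-to-end chain on a 2400-frame movie
of 1200 particles on one cell — sizes at which binomial and
Monte-Carlo errors are comfortably below the tolerances being
asserted.

## A worked example

```{r demo, eval = FALSE}
cfg <- run_config(seed = 808, sim = simulation_config(
  n_particles = 1200, frac_immobile = 0.131, D_mobile = 0.0272,
  n_frames = 2400, activation_rate = 0.55))
bundle <- run_demo(cfg, photons = 5000, background = 10)
as.data.frame(bundle$summary)
pole_surface_fraction(build_cell(5, 1), 480)
```

The summary row reports the retained-track count, immobile fraction
and mean mobile $D$ with bootstrap SDs; the last line prints 0.192,
the polar-enrichment null for a typical cell.
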