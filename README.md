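# sptpalm

Single-particle-tracking PALM (sptPALM) analysis for membrane proteins
of rod-shaped bacteria, plus a ground-truthed simulator that makes every
stage of the analysis verifiable without microscope data.

## What it does, and for whom

sptPALM sparsely photoactivates fluorescent fusion proteins so that
single molecules can be localized and followed at video rate. For
membrane-bound cell-wall enzymes (peptidoglycan synthases and
hydrolases) the two headline quantities are the **immobile fraction**
— molecules bound to the essentially stationary peptidoglycan meshwork
— and the **diffusion coefficient of the mobile population**, plus the
**polar fraction** of particles compared against the share of cell
surface the poles contain. This package is for microscopists and
quantitative biologists who have (or want to simulate) such movies and
need a tested, reproducible path from TIFF stacks to per-condition
statistics.

The pipeline:

1. **Localization** — difference-of-Gaussians detection, then
   least-squares fitting of a symmetric 2D Gaussian integrated over
   each 160 nm pixel; sub-pixel positions in nm.
2. **Linking** — globally optimal (Hungarian) one-to-one assignment
   between consecutive frames within a 320 nm gate; no gap closing;
   only tracks of 4–12 frames (0.4–1.2 s at 10 Hz) are retained.
3. **Motion analysis** — a track is immobile if its bounding box stays
   inside one pixel (160 nm); mobile tracks get a time-averaged MSD,
   an anomalous exponent from `log TAMSD = log(4D) + α · log Δt`
   (retained for 0 ≤ α ≤ 1.5), and `D` from a straight-line fit to the
   first four MSD points with a free intercept that absorbs the static
   localization-error offset.
4. **Spatial statistics** — particles are assigned to the pole
   (within 480 nm of a cell end along the centerline) or the nonpolar
   region; the analytic null is the pole share of a spherocylinder's
   surface, `2·2πrd / (2πr·L_cyl + 4πr²)` = 0.192 for a 5 × 1 µm
   cell. Mask morphometry (length, width, L/W) is included.
5. **Population statistics** — immobile fraction and mean mobile `D`
   with SDs from 1000 bootstrap resamples of whole tracks, the
   fixed-difference (> 0.005) significance rule, and one-way ANOVA
   for cell-dimension comparisons.
6. **Simulator** — Brownian motion on a spherocylindrical surface
   (tangent-plane steps + reprojection), Poisson photoactivation,
   geometric photobleaching, a hard HILO visibility slab, Gaussian
   localization noise, and camera rendering with an integrated-Gaussian
   PSF and Poisson shot noise.

## Worked example

A full synthetic round trip — simulate 1200 particles (13.1% immobile,
D = 0.0272 µm²/s) on a 5 × 1 µm cell, render 2400 frames, localize,
link, filter, analyze, summarize:

```r
library(sptpalm)
cfg <- run_config(seed = 808, sim = simulation_config(
  n_particles = 1200, frac_immobile = 0.131, D_mobile = 0.0272,
  n_frames = 2400, activation_rate = 0.55))
bundle <- run_demo(cfg, photons = 5000, background = 10)
as.data.frame(bundle$summary)
#>       label n_tracks n_immobile n_mobile_retained immobile_fraction
#> 1 synthetic      177         62                91            0.3503
#>   boot_sd_fraction  mean_D boot_sd_D n_boot     seed
#> 1          0.03513 0.02683  0.002711   1000 39736071
```

Reading the row: 177 tracks survived the 4–12-frame filter; the mean
`D` of the 91 mobile, α-retained tracks is 0.0268 ± 0.0027 µm²/s —
within 2% of the simulated truth. The raw immobile fraction (0.35)
overshoots the simulated 0.131 because genuinely mobile particles seen
for only 4–6 frames often fail to leave a 160 nm box; the vignette
quantifies this short-track bias, which cancels in between-condition
comparisons that share a track-length distribution. The spatial block
of the bundle gives the polar fraction (0.169, 30/177 tracks) against
the 0.192 surface-share null:

```r
bundle$spatial$polar_fraction   # 0.1694915
pole_surface_fraction(build_cell(5, 1), 480)  # 0.192
```

A thin CLI over the same functions lives in `inst/cli/sptpalm.R`
(subcommands `simulate`, `render`, `localize`, `track`, `analyze`,
`spatial`, `summarize`, `demo`).

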