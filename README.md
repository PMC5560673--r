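# tracker3d

Three-dimensional single-cell tracking for light-sheet fluorescence
microscopy (LSFM) time-lapses.

## The problem

LSFM can watch individual fluorescent cells — for example mesenchymal
stromal cells seeded on ~400 µm spherical microcarriers — for many hours,
as a sequence of 3D z-stacks (hundreds of slices at a 2 µm z-interval,
0.589 µm lateral sampling, one stack every 30 minutes). Quantifying how
those cells move requires turning tens of gigabytes of voxels into a few
per-cell curves: path length, distance from origin, speed.

`tracker3d` implements the projection-based strategy for that task:

1. **illumination correction** — retrospective vignetting model
   (per-pixel gain `g` and offset `o`; corrected = `(I − o) / g`);
2. **rigid alignment** of all stacks to a reference frame
   (cross-correlation of projections, clipped so moving cells cannot
   out-vote the static scene);
3. **maximum-intensity projection** (MIP) along z, with per-pixel depth
   provenance;
4. **2D tracking** on the MIPs — Gaussian-smooth / threshold / label
   detection and gated optimal-assignment linking (automatic mode), plus
   seeded (semi-automatic) and manual-import modes;
5. **z-recovery** — for each tracked point, z = argmax over slices of the
   local mean intensity at the tracked (x, y);
6. **motility metrics** in µm and µm/min, per cell and per cohort, with
   CSV / XLSX / JSON export.

For a track with positions `p_t` (µm), the package reports path length
`L = Σ_t ‖p_{t+1} − p_t‖`, distance from origin `d_t = ‖p_t − p_0‖`,
mean speed `L / (T·dt)` and straightness `‖p_T − p_0‖ / L`.

A synthetic generator (`sim_config()`, `simulate_tracks()`,
`render_timelapse()`) simulates cells walking on a microcarrier surface
with tunable directional persistence and renders them as realistic noisy
z-stacks, so every stage is validated against known ground truth — no
real data needed to test the package.

## Worked example

Simulate a 70 µm carrier bearing 5 cells over 8 half-hour frames, run the
whole pipeline, and look at the result:

```r
library(tracker3d)

cfg <- sim_config(sphere_diameter_um = 70, volume_px = c(160, 160, 48),
                  n_cells = 5, n_frames = 8, step_um = 6,
                  persistence = 0.7, seed = 27)
truth <- simulate_tracks(cfg)
tl    <- render_timelapse(truth, cfg)

run <- run_pipeline(tl, pipeline_config(seed = 27), out_dir = "results_demo")
summary(run)
#> tracker3d run (auto mode, 3d metrics)
#>   5 track(s), 40 point(s)
#>   mean path length         42.5 um
#>   mean net displacement    37.0 um
#>   mean speed              0.202 um/min
```

Each simulated cell steps 6 µm per 30-min frame, so a complete 8-frame
track covers 7 × 6 = 42 µm of true path; the recovered mean of 42.5 µm is
a ~1% error. The mean net displacement (37.0 µm) is below the path
length, reflecting the partly-wandering motion at persistence 0.7, and
0.202 µm/min ≈ 6 µm / 30 min is the per-frame step speed. Accuracy
against the ground truth can be quantified directly:

```r
ev <- evaluate_against_truth(run$tracks, truth)
round(ev$point_match_frac, 3)                     # 1 — no identity swaps
round(median(ev$points$err_xy_um), 3)             # 0.051 um lateral error
round(median(ev$points$err_z_slices), 3)          # 0.219 slices axial error
```

`plot(run)` draws the per-cell distance-from-origin curves with the
cohort average as a dotted line; `results_demo/` contains `tracks3d.csv`,
`metrics.csv`, `summary.csv`, `metrics.xlsx` and `manifest.json`.

Real data enter through `read_timelapse()` (multi-page grayscale TIFFs,
one per time point, `lazy = TRUE` for volumes larger than memory) with
the voxel geometry given by `voxel_geometry(dx, dy, dz, dt)`. A thin
command-line front end for batch use lives at `inst/scripts/tracker3d`
(subcommands `simulate` and `run`).

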