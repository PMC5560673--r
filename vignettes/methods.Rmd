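---
title: "Methods: 3D single-cell tracking from maximum-intensity projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D single-cell tracking from maximum-intensity projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Light-sheet fluorescence microscopy (LSFM) acquires 3D z-stacks of a living
sample fast enough, and gently enough, to follow individual fluorescent
cells for many hours. The motivating application is mesenchymal stromal
cells moving on the surface of a ~400 µm spherical microcarrier, imaged as
200–500 slices at a 2 µm z-interval with 0.589 µm lateral sampling, one
stack every 30 minutes, 21 stacks in a 10-hour session.

Tracking directly in 3D is expensive and unnecessary for sparse, bright,
point-like objects. This package implements the projection-based shortcut:

1. **Correct** each stack for uneven illumination (vignetting).
2. **Align** all stacks rigidly to a reference frame, so that cell
   coordinates live in one global coordinate system.
3. **Project** each stack to its 2D maximum-intensity projection (MIP);
   every pixel also remembers which slice produced its maximum.
4. **Track in 2D** on the MIPs: detect spots, then link them through time.
5. **Recover z** per tracked point as the z-plane with the highest local
   intensity at the tracked (x, y).
6. **Measure** path length, distance from origin, speed and straightness
   in physical units, per cell and per cohort.

The decomposition is exact for a single isolated cell (the MIP of a bright
spot preserves its lateral position, and the axial argmax recovers its
slice) and degrades gracefully with crowding: cells whose projections
collide can swap identity in step 4, which is why the package ships a
ground-truth simulator to quantify that degradation.

## Coordinate and time conventions

Voxel coordinates are 0-based and real-valued: the centre of the first
voxel is (0, 0, 0), x is the image column, y the row, z the slice. Frame
`time_index` k corresponds to k·dt minutes, so a 10-hour session at 30-min
intervals spans `time_index` 0..20 (21 frames). Physical coordinates are
componentwise products with (dx, dy, dz, dt); extents are reported rounded
to integer micrometres (1920 px × 0.589 µm/px → 1131 µm). Internally R
arrays are 1-based `[y, x, z]`; the boundary between the two conventions
is confined to indexing helpers.

## Illumination correction

The vignetting model is per-pixel multiplicative gain plus additive
offset. Published retrospective estimators fit this by energy
minimization; here a deliberately simple, fully documented estimator is
used, with the same contract (flatten multiplicative shading):

* `offset` = per-pixel 5% quantile across the training planes (type-1
  order statistic, index ⌈q·n⌉), Gaussian-smoothed with σ = 2% of the
  image diagonal, then clamped at the per-pixel minimum — the clamp
  guarantees no training pixel corrects below zero;
* `gain` = per-pixel median of (plane − offset), smoothed the same way,
  floored at a small positive value and normalized to unit mean.

A constant collection degenerates to gain ≡ 1 and offset ≡ the constant.
Correction is `(image − offset) / gain`, clipped at zero, applied per
slice for stacks. On planes synthesized from a known radial gain field the
estimate correlates with the truth (the test suite asserts r > 0.95;
measured ~0.997) and correction recovers the clean signal to a few
percent relative RMSE. The offset/gain decomposition is identifiable only
when the training collection spans brightness down to near-dark planes
(true of the edge slices of real stacks); otherwise the dimmest observed
level is absorbed into the offset and correction acts as a background
subtraction — still harmless for detection, but not a true flat-field.

## Rigid alignment

Lateral shifts are estimated per frame by circular cross-correlation
between the frame's MIP and the reference frame's MIP; the axial shift by
circular cross-correlation of per-slice mean-intensity profiles. Both
signals are **intensity-clipped** first (MIPs at the pooled 80th
percentile, stacks at the 98th): a handful of bright *moving* cells
otherwise dominates the correlation and the estimator follows the cells
instead of the stage. Clipping leaves the extended static structure — the
carrier itself, which is faintly visible in real acquisitions — in charge
of registration. This is the package's main deviation from plain phase
correlation, whose spectral whitening amplifies exactly the sparse moving
features we need to ignore.

The peak gives integer shifts; ties break towards the smallest-magnitude
shift, and the confidence (the normalized correlation coefficient at the
peak) must exceed `min_confidence` (default 0.3), else the frame keeps a
zero shift with a warning. Stacks are resampled trilinearly with zero
fill; integer shifts reproduce voxels exactly. An optional user-supplied
in-plane rotation is applied before estimation (manual override for
deliberately rotated acquisitions). Correction runs before alignment by
default; the two stages commute in practice for smooth gain fields, and
correcting first means registration sees flattened images.

## Projection

The MIP is the default. `argmax_z` stores, per pixel, the lowest slice
attaining the maximum — the deterministic tie-break matters only for
saturated or constant columns. The extended-depth-of-field alternative
scores each slice by local intensity variance in a `patch`-sized window,
median-filters the winning-slice map with the same window, and samples the
stack there; it is opt-in (`projection = "edf"`) because the MIP is the
method's published default path and the EDF operator in the cited
literature is not specified beyond "full focus".

## 2D detection and linking

Detection is smooth (Gaussian, `sigma_px` = 2) / threshold (Otsu by
default, absolute as override) / label (8-connected components) / filter
(`min_area`..`max_area`) with intensity-weighted centroids on the
smoothed image. There is no learned or appearance-based component; for
point-like cells at the SNR of calcein-labelled LSFM this reaches ~0.1 px
centroid accuracy on synthetic spots.

Linking is frame-to-frame gated optimal assignment: candidate pairs must
lie within `gate_px` per elapsed frame; among gated pairs the Hungarian
algorithm maximizes the number of links and then minimizes total squared
displacement. The two-level objective is implemented with an unmatch
penalty larger than any feasible matched cost, and is verified exactly
against a brute-force enumeration oracle on small random instances.
Unmatched detections open new tracks; a track missing ≤ `max_gap` frames
is re-linked across the gap (with the gate scaled by the elapsed frames)
and the gap is bridged by linearly interpolated points flagged
`gap-filled`. Gap-filled points are excluded from motility measures by
default — interpolation should not fabricate motion.

Two additional modes honour how such tools are used in practice:
semi-automatic (`seeded_track`: follow an intensity-weighted centroid
within a search radius from user-supplied starting points, stopping when
the local maximum drops below the detection threshold) and manual import
(verbatim CSV, validated and flagged `manual`).

## z-recovery

For each tracked point the score of slice z is the mean intensity within
a disk of `window_radius_px` (default 3 px) around the tracked position;
z is the lowest slice attaining the maximum score. Radius 3 resists
single-pixel noise; radius 0 reproduces the literal per-pixel argmax of
the stack column (verified against a brute-force oracle). Integer slices
are the default output; parabolic sub-slice refinement through the three
scores around the peak is available but off by default, since slice-level
precision is what the acquisition geometry supports. `z_confidence`
(peak score / median score along the column) flags points whose column
has no real axial structure.

## Motility measures

All measures are 3D Euclidean in micrometres (anisotropic scaling before
distances); a 2D mode ignores z for comparison with projection-only
analyses. Per track: path length (sum of step lengths), distance from
origin (per time point, from the first retained point), instantaneous and
mean speed (µm/min), net displacement, and straightness (net/path, defined
as 1 for a zero-length path). Cohort summaries average each measure per
time point over the tracks defined there — no imputation; the averages are
the dotted black line in the standard per-cell motility plot
(`plot(run)`). The triangle inequality (distance from origin never exceeds
accumulated path) holds by construction and is asserted as a property test;
it is worth noting that published cohort numbers occasionally violate it,
which can only be a reporting artifact and is not something a correct
implementation can or should reproduce.

Exports: `tracks3d.csv`, `metrics.csv` (long), `summary.csv` (per track),
`metrics.xlsx` (a minimal OOXML workbook written without external
spreadsheet libraries, one sheet per table) and `manifest.json` (inputs,
parameters, version, seed). CSV re-export under identical inputs is
byte-identical.

## The synthetic generator

The simulator is the package's validation substrate, not an afterthought:
it generates ground-truth trajectories *and* renders them through the same
image formation the pipeline assumes.

* **Motion.** Cells start uniformly on the carrier sphere and move along
  great circles with per-step *chord* length exactly `step_um`; the
  direction mixes the parallel-transported previous direction with a
  uniform random tangent, weighted by `persistence`. Persistence 0 gives
  the wandering, returning behaviour of freshly seeded cells; persistence
  near 1 the straight runs of polarized cells — the two regimes differ by
  more than 2× in final distance from origin at equal path length, which
  is exactly the day-1 vs day-3 contrast the measures are designed to
  expose. The chord parameterization makes the persistence-1 closed forms
  exact: path = k·s, distance from origin = 2r·sin(k·asin(s/2r)).
* **Rendering.** Each cell is an anisotropic 3D Gaussian (σ_xy = 2 µm,
  σ_z = 4 µm, amplitude 3000) over background 100; the carrier shell is
  rendered as a faint Gaussian ridge (amplitude 40) — it is visible in
  real acquisitions and is the static structure alignment locks onto;
  every plane is multiplied by the radial vignetting field
  1 − s·(r/r_max)²; Poisson shot noise is drawn on the expected counts,
  Gaussian read noise (σ = 5) added, and the result quantized to 16 bit.
  No depth attenuation or scattering is modelled (the carrier is
  transparent), no stripe artifacts, no cell division or shape change:
  passing tests demonstrate correctness of the geometry, linking and
  measurement chain, not robustness to every LSFM artifact.
* **Scale.** The default validation fixture uses a 240 µm carrier inside
  a 512 × 512 × 150 voxel volume at the true acquisition voxel size —
  the same optical geometry at a desk-friendly field of view (the full
  1920 × 1920 × 500 volume would hold the 400 µm carrier, and
  `sim_config()` defaults to that carrier with an auto-fitted volume).
  Step length defaults to 10 µm/frame so that a 21-frame session covers
  ~200 µm of path, the order of magnitude reported for MSCs on
  microcarriers.

## Numerical choices and degenerate inputs

* Ties: argmax tie-breaks are always "lowest index" (slices) or
  "smallest magnitude" (shifts); assignment ties are broken by the
  deterministic Hungarian implementation. Reruns are bit-identical.
* The registration confidence threshold (0.3) separates, by an order of
  magnitude, genuine static-structure correlation (~0.9 on the synthetic
  fixture) from the noise floor of unrelated frames.
* Blank frames detect zero cells; single-point tracks have zero path
  length and straightness 1; empty cohorts export header-only tables.
* Quantile conventions (offset order statistic, clipping quantiles) are
  stated in the function documentation and asserted in tests, since
  "the 5% quantile" is otherwise ambiguous across implementations.
* The full-volume test sizes (512 × 512 × 150 × 21 frames, 15 cells) were
  chosen so the complete validation cycle — simulate, render, track,
  compare to truth — runs comfortably on a single CPU.

## Known limitations

* Identity preservation degrades when two cells' projections overlap for
  several consecutive frames; the evaluator (`evaluate_against_truth`)
  quantifies this, and crowded cohorts should be interpreted with the
  reported match fraction in mind.
* The axial argmax assumes one dominant emitter per tracked column; two
  cells stacked along z resolve to the brighter one.
* Alignment is rigid (translation + optional fixed rotation); slow
  non-rigid sample drift is outside the model.
* The illumination estimator assumes shading that is smooth at the 2%
  image-diagonal scale; it will not remove pixel-scale fixed-pattern
  noise.
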