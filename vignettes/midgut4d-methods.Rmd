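---
title: "Methods: quantifying division, differentiation and loss in 4D midgut movies"
author: "midgut4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying division, differentiation and loss in 4D midgut movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midgut4d)
```

# Scope and conventions

midgut4d quantifies the three core behaviors of adult *Drosophila* midgut
renewal — stem-cell division, Notch-driven enteroblast differentiation, and
enterocyte loss by apical extrusion — from tracked-nuclei exports of
long-term volumetric movies. All analysis happens in physical micrometres in
a right-handed space: x–y is the image plane, z the optical axis. Frame
indices are 0-based; times are minutes from movie start. Typical
acquisitions are 12–16 h with 5–15 min between z-stacks, a z-step near
3 µm, and 100–300 cells in the field.

The contract with upstream imaging software is a documented CSV track
schema (one row per living cell per time point: 3D centroid, nuclear
volume, raw CFP/GFP/RFP intensities), plus annotation tables for
extrusion-ring vertices, basal-plane reference points, and mitosis records.
Reading proprietary microscope or commercial-tracker formats is out of
scope.

# Cell typing

The four major cell types are distinguished by combinatorial nuclear
reporters: stem cells are CFP+RFP+, enteroblasts CFP+GFP+RFP+, mature cells
(enterocytes and enteroendocrine cells) RFP only. `mask_populations()`
reproduces the image-calculator recipe — stem = CFP AND NOT GFP,
enteroblast = GFP, mature = RFP AND NOT CFP — which partitions the nuclear
foreground whenever every CFP+ voxel is also RFP+ (true of the genotype,
since RFP is ubiquitous). Mature nuclei are split by `classify_mature()` at
113 µm³ of nuclear volume: at or below the cutoff enteroendocrine (small,
diploid), above it enterocyte (large, polyploid). The boundary value is
assigned to the enteroendocrine side.

Nucleus segmentation (`segment_nuclei()`) is intensity thresholding of the
ubiquitous nuclear channel followed by 3D connected-component labeling
(26-connectivity by default; compact nuclear blobs rarely bridge
diagonally, and residual specks are removed by a minimum component volume,
default 20 µm³). Volumes are voxel count × voxel volume; centroids are
intensity-weighted voxel means converted to µm. Thresholds are either
automatic (Otsu per channel) or fixed: the original workflow used
operator-chosen manual thresholds, whose values are not stated, so both
modes are supported and fixed thresholds are recommended for
reproducibility.

# Tracking

`link_tracks()` is a deterministic stand-in for commercial Brownian-motion
trackers: per consecutive frame pair, open track heads and new detections
are matched by greedy mutual nearest neighbors, linking only below a
displacement gate, with ties broken by (distance, lower index). At 5–15 min
sampling and the observed sub-µm/frame nuclear motility, mutual-NN linking
is essentially error-free (the test suite requires ≥ 99% link recovery on
rendered synthetic movies); equivalence with any specific commercial
tracker is not claimed, and daughters of a division begin as new tracks,
with mother/daughter association carried by annotation, since mitoses were
identified by inspection in the original workflow.

Progenitor pairs are defined exactly as in the calibration analysis: two
esg+ cells form a pair when each is the other's nearest esg+ neighbor.

# Extrusion-ring morphometry

The basal junctional ring of an extruding enterocyte is annotated as six
ordered vertices per frame plus three reference points on the basal
epithelial surface. `fit_basal_plane()` turns the reference points into a
unit normal (cross product of two edge vectors), oriented apical-positive
via an orientation hint. `ring_area()` triangulates the polygon as a fan
around its centroid; each triangle contributes half the norm of the cross
product of the two centroid-to-vertex vectors. This is exact for planar
convex polygons and well-defined for the slightly non-planar rings real
annotations produce. `ring_footprint()` projects the ring orthogonally onto
the basal plane and returns 2D in-plane coordinates, so successive frames
can be overlaid; `plane_distance()` is the signed orthogonal
centroid-to-plane distance (apical positive).

## Ratchet-pulse decomposition

Ring closure is ratcheted: constriction pulses alternate with
relaxation/stabilization pulses, with net inward progress. The original
report shows pulses lasting tens of minutes, 6–12 alternations per event,
cumulative constriction and relaxation times of similar magnitude, and
constriction rates generally exceeding relaxation rates. The pulse
criteria themselves are not stated, so `detect_pulses()` makes the
following declared choices:

* **Detection scale.** When all areas are positive, detection runs on
  log-area. Both annotation noise (vertex-placement error moves area
  roughly in proportion to ring size) and pulse amplitudes (junctional
  tension scales with ring size) shrink as the ring closes, so the log
  scale makes the decomposition scale-invariant. Monotone transforms
  preserve segment boundaries, so noiseless recovery is unaffected.
* **Turning points with hysteresis.** The series is scanned once; a
  direction reversal is committed only when the series retraces more than
  `hysteresis` (default 0.12 in log units, i.e. a pulse must move the area
  by at least ~13%) from its running extremum. Observed pulses change the
  area severalfold, while a few percent of annotation noise stays well
  below the bar, so the default separates the two regimes by a wide
  margin. The test suite verifies exact pulse-count recovery at zero noise
  and ±1 at 5% multiplicative area noise for 6–12 scheduled pulses.
* **No smoothing by default.** At 5–15 min sampling a pulse segment spans
  only 2–6 frames; a centered moving average attenuates such short
  segments below any workable hysteresis while the hysteresis already
  supplies the noise robustness. A `window` argument remains for
  oversampled series.
* **Boundary refinement and labeling.** Segment boundaries snap to the
  local raw-series extremum near each turning point (removing any
  smoothing lag), mean rates dA/dt are computed from the raw series over
  each segment, and segments are labeled constriction when the
  detection-scale rate falls below a dead-band `epsilon` (5% of the
  maximum absolute rate), everything else — including flat stabilization —
  counting as relaxation. Adjacent same-kind segments are merged so kinds
  alternate, and cumulative times per kind are reported.

## Nuclear travel

`nuclear_travel()` measures the apical ejection of the extruding nucleus
from its per-frame signed distance to the basal plane: baseline = median of
an initial window; onset = first frame exceeding baseline by
max(2 × MAD, 0.5 µm) for ≥ 2 consecutive frames; peak = distance maximum;
duration = peak − onset; recoil = peak minus the final plateau (median of
the last 3 frames). The 0.5 µm floor keeps a noiseless flat series from
triggering on numerical dust. A monotone-flat series returns a flagged
no-event result.

# Division orientation and mitotic index

Mitosis runs from nuclear condensation in the mother to decondensation of
the daughter chromosomes; durations in vivo are 30–60 min. The mitotic
index is T_M/T_SC: summed mitosis durations over summed stem-cell 'screen
time' (stem count at t = 0 × movie duration, summed over movies;
appearances/disappearances mid-movie are ignored). When a movie lacks
fate markers the stem count is estimated as 20% of its nuclei.

Angles are reported in three frames, all folded into [0°, 90°] because the
axes involved are undirected:

* `angle_hv()`: angle between the spindle-pole axis and the basal plane
  (0° horizontal, 90° vertical), computed as 90° minus the angle to the
  unit normal. The identity `angle_hv + angle_to_normal = 90°` holds
  exactly and is tested.
* `angle_lc()`: angle between the daughter–daughter axis and the local
  longitudinal tube axis (0° longitudinal, 90° circumferential). Passing
  the plane normal projects both vectors in-plane first, matching
  measurements made on projected images. The longitudinal axis is supplied
  per mitosis (determined by inspection of tube morphology in real data;
  analytically from tube geometry in the simulation).
* `angle_eb()`: for divisions contacting enteroblasts, the angle between
  the EB→D1 and D1→D2 vectors, where the reference EB is the sole
  contacting one or, with two, the one closer to the mother before
  division, and D1 is the daughter closer to the reference EB. Equidistant
  ties are broken deterministically (lower index) and flagged. Mitoses
  contacting enteroblasts are conventionally excluded from
  horizontal-vertical and planar summaries.

`reorientation_events()` counts frame-to-frame orientation changes at or
above a threshold (≥ 15° and ≥ 30° are the conventional bars).

# Notch-activation metrics

Notch pathway activation is read as GFP:RFP — a Notch transcriptional
reporter over a ubiquitous nuclear reference. `normalize_ratios()` first
scales each channel to 0–1 per movie by dividing by that channel's maximum
over **all** cells and frames of the movie, then forms the per-cell,
per-frame ratio of normalized GFP to normalized RFP. The metric is exactly
invariant to per-movie multiplicative gain; zero-RFP frames are flagged
invalid rather than propagated as infinities. A robust quantile option
exists but is off by default, matching the published protocol's literal
maximum.

`estimate_threshold()` estimates the stem/enteroblast fate threshold as
the density minimum between the two modes of the pooled ratio
distribution: Gaussian KDE with Silverman bandwidth on values clipped to
[0, 2], threshold reported at 0.001 resolution. Two guards distinguish
genuine bimodality from sampling wiggles: a second mode must reach ≥ 5% of
the main peak's height, and the valley between the modes must fall below
80% of the smaller peak. With neither satisfied the distribution is
declared unimodal and no threshold exists. The threshold's absolute value
is imaging-system-specific (0.17 in the published system); 0.17 is
retained only as a fallback default where no estimate is available.

`detect_transitions()` scores a cell as undergoing an enteroblast
transition when its ratio persistently rises from below to at-or-above the
threshold: the crossing is the first frame at/above threshold that stays
there for 3 consecutive valid frames (rejecting single-frame noise at
5–15 min sampling), and reaching the threshold counts as crossing. The
baseline time is the foot of the rise, found in two phases: the last
pre-crossing frame near the low pre-crossing level (10th percentile plus a
quarter of the headroom to threshold), then walking back down the rise
while the series decreases. On a noiseless flat-then-ramp series this
lands exactly on the last flat frame, which reproduces the published
worked example (baseline 0.049 at 3.5 h, crossing at 10.4 h, duration
6.9 h); a pre-crossing local-minimum rule, the obvious alternative, fails
under realistic noise because the last local minimum sits just before the
crossing. The baseline value is the median of up to 6 frames ending at the
baseline time; cells entirely above threshold are flagged
`already_enteroblast`, and persistent falls from above to below are
reported as reversion candidates.

Sibling contact is inferred from inter-nuclear distance, calibrated
against membrane markers: < 6.0 µm contact, > 15.5 µm separated, the
closed interval between (both boundaries included) indeterminate — a
total partition of [0, ∞). `sibling_contact_timeline()` classifies a
pair's common frames and summarizes the state sequence: the longest
maximal separated run (a pair 'separated ≥ 1 h' has such a run spanning
≥ 60 min), the number of direct contact↔separated alternations
(indeterminate frames ignored), and whether separation appears permanent
(final maximal run separated, reaching the end of co-observation).
`flag_bleedover()` invalidates frames where a cell sits within 6 µm of a
neighbor with ratio > 0.5, the signature of GFP bleed-over during
collisions with bright enteroblasts; flagged frames are excluded from
transition calling but retained in outputs.

# The synthetic world

`generate_tracks()` emulates the statistical structure the analyses
assume, not microscopy per se. Design choices, fixed once:

* **Geometry.** Nuclei sit on a cylindrical surface (radius 60 µm, the
  imaged band ±0.8 rad around the objective-facing side, default field
  400 µm long) and perform a reflected random walk in unrolled surface
  coordinates (SD 0.3 µm/frame) — the epithelium is a monolayer, and the
  surface parameterization keeps the horizontal-vertical and
  longitudinal-circumferential frames well defined. Cells are placed by
  rejection sampling with a 12 µm minimum spacing; the defaults put
  ~120 cells in the field, inside the observed 100–300 range.
* **Types and volumes.** Exact quotas by default (20% stem, 15%
  enteroblast, 10% enteroendocrine, remainder enterocyte) so tests are
  deterministic; a binomial mode exists. The stem:enteroblast default of
  4:3 matches the reported mass ratio of the two ratio modes. Volumes:
  stem/enteroblast 50–110 µm³, enteroendocrine 35–80 µm³, enterocyte
  180–500 µm³ — diploid versus polyploid nuclei with a deliberate margin
  around the 113 µm³ filter, so size classification is tested on sizes,
  not on borderline rasterization error. (Real late enteroblasts
  endoreplicate and can exceed the cutoff; the generator keeps
  progenitors small by construction.)
* **Intensities.** Raw intensity = amplitude × per-movie channel gain +
  Gaussian noise (gains drawn in 800–1600 unless pinned), so cross-movie
  normalization is genuinely exercised. Scheduled GFP:RFP ratios are
  bimodal: stem mode 0.015, enteroblast mode 0.528, with each mode's
  width split evenly between cell-to-cell and temporal variation (both
  exist in real data; temporal variation also makes two movies' pooled
  distributions agree at the Kolmogorov–Smirnov level the tests require).
  Stem ratios are clamped below 0.12 so a stem cohort is bounded below
  any plausible threshold. Each movie carries two anchor nuclei — a
  brightest-RFP nucleus at the amplitude ceiling and one bright late
  enteroblast (ratio 1.2–1.6, within the observed 0–1.8 range) at the
  GFP ceiling — so per-movie maximum normalization returns the scheduled
  ratios exactly at zero noise, giving clean round-trip oracles.
* **Events.** Mitoses place spindle poles so scheduled
  horizontal-vertical / longitudinal-circumferential angles hold exactly
  on the local tangent plane; daughters appear at decondensation,
  separated 5 µm along the final spindle axis. Extrusions follow an
  alternating piecewise-linear ring-area schedule whose pulse amplitudes
  ride the closing ladder (each constriction multiplies area by a fixed
  factor, each relaxation recovers half of it on the log scale; net
  closure to 2%): pulse size scaling with ring size is the physically
  sensible regime and keeps every pulse equally detectable under
  proportional annotation noise — with equal-amplitude pulses, early
  relaxations at high pulse counts would be statistically invisible at
  5% noise and no detector could recover them. Transitions hold a flat
  baseline then ramp linearly with a recorded threshold-crossing time.
  Sibling pairs realize scheduled per-frame contact states as distances
  (4 / 10 / 20 µm); collisions move a bright mature enteroblast within
  3 µm of a target cell over a scheduled window. One cell can take part
  in at most one event; collisions of schedules are rejected rather than
  merged so ground truth stays unambiguous.
* **Rendering.** `render_volume()` draws each nucleus as a sphere of its
  true volume with a Gaussian-blurred edge (half-maximum crossing exactly
  at the nominal radius), at the cell's raw channel intensity, on the
  acquisition grid (z-step 2.98 µm, ~1 µm laterally). The blurred-ball
  default means any mid-edge threshold recovers the voxel-count volume;
  a pure Gaussian profile is available (and is used to validate mean
  intensities against numeric integration), but as a default it would
  make thresholded volume depend strongly on per-cell brightness,
  confounding the size filter. The renderer emulates neither
  photorealistic optics nor peristalsis/drift (registration is out of
  scope), so green end-to-end tests establish correctness of the
  measurement chain, not robustness to uncorrected tissue motion.

What a green suite does establish: the geometry operators agree with
independent brute-force oracles; every scheduled event is recovered by its
analysis operation at zero noise (pulse counts and boundaries, angles to
1e-6°, crossing times within one frame, contact states exactly); and the
rendered imaging route recovers ≥ 95% of type labels and ≥ 99% of links at
default noise. What it does not establish: performance on real microscopy
with segmentation artifacts, touching nuclei (no watershed splitting), or
residual registration error.

# Numerical choices and degenerate inputs

Collinear basal-plane points (triangle area < 1e-9 µm²) are an error, as
are coincident spindle poles or daughters. Rings need ≥ 3 vertices.
Constant distance series yield flagged no-event travel results; constant
area series yield a single relaxation/stabilization segment; strictly
monotone decreasing series a single constriction. The transition crossing
comparison uses a 1e-9 tolerance so that series constructed to reach the
threshold exactly are not pushed a frame late by floating-point rounding.
Contact boundaries 6.0 and 15.5 µm classify as indeterminate (closed
interval, as calibrated). Mitotic frame windows include both endpoints, so
a 45-min mitosis at 7.5-min sampling spans 7 frames.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → Notch → divisions → extrusion →
contacts and writes CSV tables, a JSON report, and a manifest with the
package version, seed, config digest and file checksums. Reports contain
no timestamps, so identical seeds give byte-identical reports; a rerun in
the same directory with an unchanged config digest reuses the simulated
tables (caching never changes results, which is tested). The CLI
(`inst/cli/midgut4d.R`) wraps the same functions for shell use.

# Known limitations

* The fate threshold is imaging-system-specific; cross-study comparisons
  need re-estimation, not the 0.17 fallback.
* Mutual-NN linking has no gap-closing global optimization; occlusions
  longer than `allow_gap` frames split tracks.
* Pulse decomposition assumes pulses of at least ~13% relative amplitude;
  genuinely smaller ripples are, by design, treated as stabilization.
* The manual 5-criterion viability screen of the original workflow is a
  QC checklist outside the computational scope: wholesale dimming of
  fluorescence, mass enterocyte extrusion (> 12 cells at once), loss of
  ordered enterocyte packing, multiple pyknotic nuclei, or widespread
  progenitor flattening each invalidate the remainder of a movie.
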