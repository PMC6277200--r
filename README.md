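# midgut4d

Quantitative analysis of long-term 4D (x, y, z, t) live-imaging movies of the
adult *Drosophila* midgut epithelium.

Extended live imaging of the midgut — hours-long multichannel confocal
z-stacks of a genetically labeled epithelium — makes it possible to watch the
three core behaviors of organ renewal in real time: stem-cell division,
enteroblast differentiation, and enterocyte loss by apical extrusion. Turning
those movies into numbers requires a chain of specialized measurements that
this package implements as tested, reusable functions:

* **Cell typing from combinatorial nuclear reporters.** Nuclei are segmented
  by intensity thresholding of a ubiquitous nuclear marker
  (`segment_nuclei()`), split into stem / enteroblast / mature populations by
  channel-mask arithmetic (`mask_populations()`: stem = CFP AND NOT GFP,
  enteroblast = GFP, mature = RFP AND NOT CFP), and mature nuclei are divided
  into enteroendocrine (volume ≤ 113 µm³) and enterocyte (> 113 µm³) by a
  nuclear-size filter (`classify_mature()`).
* **Tracking.** Frame-to-frame linking of detections by mutual nearest
  neighbors under a displacement gate (`link_tracks()`), and the
  mutual-nearest-neighbor definition of progenitor pairs
  (`find_progenitor_pairs()`).
* **Extrusion-ring morphometry.** The junctional ring of an extruding
  enterocyte is summarized by its fan-triangulated cross-sectional area
  (`ring_area()`; each triangle is half the cross product of the two vectors
  from the polygon centroid to adjacent vertices), its footprint projected
  onto the basal plane (`ring_footprint()`), and the signed orthogonal
  distance of the nucleus from the basal plane (`plane_distance()`). Ring
  closure is decomposed into alternating ratchet pulses of constriction and
  relaxation (`detect_pulses()`), and nuclear ejection/recoil kinetics are
  measured by `nuclear_travel()`.
* **Division orientation.** Mitosis durations (condensation →
  decondensation), the mitotic index T_M/T_SC (summed mitosis time over
  summed stem-cell screen time, `mitotic_index()`), and division angles in
  three frames of reference: horizontal–vertical relative to the basal plane
  (`angle_hv()`, 0° = horizontal), longitudinal–circumferential relative to
  the tube axis (`angle_lc()`), and relative to contacting enteroblasts
  (`angle_eb()`), plus counting of spindle re-orientation events
  (`reorientation_events()`).
* **Notch-activation fate dynamics.** Per-movie max-normalized GFP:RFP
  reporter ratios (`normalize_ratios()`), estimation of the bimodal fate
  threshold as the density minimum between the stem and enteroblast modes
  (`estimate_threshold()`), benchmark validation against known (pre-mitotic)
  stem cells (`benchmark_stem_fraction()`), enteroblast transition calling
  with a persistence rule (`detect_transitions()`), inter-nuclear-distance
  contact inference (contact < 6.0 µm, separated > 15.5 µm,
  `classify_contact()`, `sibling_contact_timeline()`), and bleed-over
  flagging for cell collisions (`flag_bleedover()`).
* **Synthetic movies with ground truth.** `sim_config()` /
  `generate_tracks()` emulate a curved epithelial monolayer of tracked
  nuclei (~20% stem cells, bimodal GFP:RFP with modes near 0.015 and 0.528,
  mitoses of 30–60 min, ratcheted extrusions closing over 4–6 h, sibling
  pairs with scheduled contact states), and `render_volume()` rasterizes
  them into multichannel image stacks so segmentation and tracking can be
  validated end to end. Every scheduled event carries a complete
  ground-truth record.
* **Pipeline.** `run_pipeline()` orchestrates simulate → analyze → report
  with caching and a run manifest; `inst/cli/midgut4d.R` exposes the same
  steps as a command-line tool.

## Worked example

```r
library(midgut4d)

cfg <- sim_config(rng_seed = 42, n_cells = 150, n_frames = 96,
                  transitions = list(list(t_start_min = 180, baseline = 0.05,
                                          final = 0.45)),
                  mitoses = list(list(t_condense_min = 120, duration_min = 45)),
                  extrusions = list(list(start_min = 60, closure_min = 300,
                                         n_pulses = 8)))
gen <- generate_tracks(cfg)

ratios <- normalize_ratios(gen$tracks)
est <- estimate_threshold(ratios$ratio[ratios$valid])
cat(sprintf("estimated fate threshold: %.3f (modes %.3f / %.3f)\n",
            est$threshold, est$modes[1], est$modes[2]))

calls <- detect_transitions(ratios, threshold = est$threshold)
calls[calls$status == "transition",
      c("cell_id", "baseline_ratio", "crossing_min", "duration_hr")]

rs <- split(gen$rings, gen$rings$frame)
areas <- sapply(rs, function(s)
  ring_area(as.matrix(s[order(s$vertex_index), c("x_um", "y_um", "z_um")])))
tm <- sapply(rs, function(s) s$t_min[1]); o <- order(tm)
pulses <- detect_pulses(tm[o], areas[o])
cat(sprintf("ring closes from %.0f to %.1f um^2 through %d constriction pulses\n",
            areas[o][1], areas[o][length(areas)],
            sum(pulses$kind == "constriction")))

n_stem <- sum(gen$tracks$label[gen$tracks$frame == 0] == "stem")
mi <- mitotic_index(45, data.frame(stem_count = n_stem,
                                   duration_min = 95 * 7.5))
cat(sprintf("mitotic index T_M/T_SC: %.4f (%.2f%%)\n", mi, 100 * mi))
```

Output:

```
estimated fate threshold: 0.198 (modes 0.024 / 0.598)
  cell_id baseline_ratio crossing_min duration_hr
3    c014     0.04495684        412.5       3.375
ring closes from 250 to 5.0 um^2 through 8 constriction pulses
mitotic index T_M/T_SC: 0.0021 (0.21%)
```

Reading this: the pooled GFP:RFP distribution of the simulated progenitors
is bimodal with a stem mode near 0.02 and an enteroblast mode near 0.6,
separated by a density minimum at 0.198 — the movie-specific fate threshold
(the printed value depends on the imaging system; in published data it was
0.17). The one scheduled slow Notch-activation event is called on cell
`c014`: its ratio leaves a baseline of ~0.045 and reaches the threshold at
t = 412.5 min, a transition lasting 3.4 h, inside the observed multi-hour
range. The scheduled extrusion's junctional ring closes to 2% of its
initial area through exactly the 8 scheduled constriction pulses, and one
45-min mitosis among 30 stem cells watched for 712.5 min gives a mitotic
index of 0.21%, the right order for homeostatic midgut imaging.

## Acceptance runner

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full synthetic pipeline end to end with the given seed (simulation,
Notch metrics with threshold estimation and transition calling, division
summaries and mitotic index, extrusion morphometry with ratchet
decomposition and nuclear-travel kinetics, sibling-contact summaries) and
writes the target report to `--out`; the detailed pipeline report lands in a
temporary run directory printed on completion.

## Layout

- `R/` — implementation (simulation, I/O, segmentation/typing, tracking,
  extrusion geometry, division orientation, Notch fates, pipeline).
- `src/` — 3D connected-component labeling (Rcpp).
- `tests/testthat/` — unit, property and acceptance suites.
- `vignettes/midgut4d-methods.Rmd` — the methods vignette: models,
  conventions, parameter choices, limitations.
- `inst/cli/midgut4d.R` — command-line entry point.
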