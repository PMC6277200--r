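#' Configuration for the synthetic midgut movie generator
#'
#' The generator emulates the statistical structure of tracked-nuclei exports
#' from long-term midgut movies: a curved epithelial monolayer (nuclei on a
#' cylindrical surface) of ~100-300 cells imaged every 5-15 min for 12-16 hr,
#' with ~20% stem cells, nuclear volumes per cell type (mature nuclei <= 113
#' um^3 are enteroendocrine), and a bimodal normalized GFP:RFP structure with
#' a sharp stem mode near 0.015 and a broad enteroblast mode near 0.528.
#' Scheduled events (mitoses, extrusions, Notch-activation transitions,
#' sibling pairs, bleed-over collisions) each carry a complete ground-truth
#' record so analysis operations can be validated by parameter recovery.
#'
#' Raw intensities follow `amplitude x movie gain + Gaussian noise`, with a
#' different gain per movie so cross-movie normalization is actually
#' exercised. Each movie contains an anchor nucleus at the RFP amplitude
#' ceiling and (when enteroblasts exist) a bright late enteroblast whose GFP
#' amplitude sits at the GFP ceiling, so per-movie maximum normalization
#' recovers the scheduled ratios exactly at zero noise.
#'
#' @param rng_seed Integer seed; identical configs give identical output.
#' @param movie_id Movie identifier.
#' @param n_cells Number of cells present at t = 0 (> 0).
#' @param stem_fraction,eb_fraction,ee_fraction Type fractions (enterocytes
#'   take the remainder). Defaults 0.20 / 0.15 / 0.10.
#' @param type_assignment `"quota"` (exact counts, default) or `"binomial"`.
#' @param frame_interval_min Minutes between frames (default 7.5).
#' @param n_frames Number of frames (default 96, a 12-hr movie).
#' @param tube_radius_um Midgut tube radius (default 60).
#' @param band_half_rad Half-width of the imaged circumferential band in
#'   radians (default 0.8).
#' @param field_length_um Longitudinal extent of the field (default 400).
#' @param min_spacing_um Minimum inter-nuclear spacing at placement
#'   (default 12).
#' @param motion_sd_um Random-walk step SD per frame, per unrolled axis
#'   (default 0.3).
#' @param voxel_size_um Voxel size `(z, y, x)` um for rendering (default
#'   `c(2.98, 1, 1)`, the acquisition z-step and ~1 um lateral resolution).
#' @param ratio_modes GFP:RFP mode locations (default `c(0.015, 0.528)`).
#' @param ratio_mode_sds Mode spreads (default `c(0.03, 0.15)`; the stem
#'   mode is sharp, the enteroblast mode broad).
#' @param intensity_noise_sd Intensity noise SD relative to the channel gain
#'   (default 0.01; set 0 for exact round trips).
#' @param gains Named numeric `c(cfp=, gfp=, rfp=)` channel gains; drawn
#'   uniformly in `[800, 1600]` when NULL.
#' @param mitoses,extrusions,transitions,sibling_pairs,collisions Event
#'   lists; see [generate_tracks()]. A cell may appear in at most one event.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rng_seed = 1L, movie_id = "sim01", n_cells = 120L,
                       stem_fraction = 0.20, eb_fraction = 0.15,
                       ee_fraction = 0.10,
                       type_assignment = c("quota", "binomial"),
                       frame_interval_min = 7.5, n_frames = 96L,
                       tube_radius_um = 60, band_half_rad = 0.8,
                       field_length_um = 400, min_spacing_um = 12,
                       motion_sd_um = 0.3, voxel_size_um = c(2.98, 1, 1),
                       ratio_modes = c(0.015, 0.528),
                       ratio_mode_sds = c(0.03, 0.15),
                       intensity_noise_sd = 0.01, gains = NULL,
                       mitoses = list(), extrusions = list(),
                       transitions = list(), sibling_pairs = list(),
                       collisions = list()) {
  type_assignment <- match.arg(type_assignment)
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("'n_cells' must be >= 1")
  fr <- c(stem_fraction, eb_fraction, ee_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("type fractions must lie in [0, 1] and sum to at most 1")
  stopifnot_scalar_num(frame_interval_min, "frame_interval_min", positive = TRUE)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  if (any(ratio_modes < 0)) stop("ratio mode locations must be >= 0")
  if (ratio_modes[1] >= ratio_modes[2]) stop("ratio modes must be increasing")
  stopifnot_scalar_num(tube_radius_um, "tube_radius_um", positive = TRUE)
  structure(list(rng_seed = as.integer(rng_seed), movie_id = movie_id,
                 n_cells = n_cells, stem_fraction = stem_fraction,
                 eb_fraction = eb_fraction, ee_fraction = ee_fraction,
                 type_assignment = type_assignment,
                 frame_interval_min = frame_interval_min, n_frames = n_frames,
                 tube_radius_um = tube_radius_um,
                 band_half_rad = band_half_rad,
                 field_length_um = field_length_um,
                 min_spacing_um = min_spacing_um, motion_sd_um = motion_sd_um,
                 voxel_size_um = as.numeric(voxel_size_um),
                 ratio_modes = as.numeric(ratio_modes),
                 ratio_mode_sds = as.numeric(ratio_mode_sds),
                 intensity_noise_sd = intensity_noise_sd, gains = gains,
                 mitoses = mitoses, extrusions = extrusions,
                 transitions = transitions, sibling_pairs = sibling_pairs,
                 collisions = collisions),
            class = "sim_config")
}

# truncated-normal draw by rejection (ranges here are wide; cheap)
.rtrunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# -- cylinder geometry ------------------------------------------------------
# Unrolled surface coordinates are (x, s): x longitudinal (um), s arc length
# along the circumference (um), s = 0 at the bottom of the tube (nearest the
# objective). The epithelium is a monolayer so nuclei live on the surface.

.sim_embed <- function(xs, config) {
  R <- config$tube_radius_um
  phi <- xs[, 2L] / R
  cbind(x_um = xs[, 1L],
        y_um = (R + 10) + R * sin(phi),
        z_um = (R + 10) - R * cos(phi))
}

# local frame at unrolled position: longitudinal u, circumferential v,
# apical normal n (pointing into the lumen, away from the objective)
.sim_frame <- function(xs_row, config) {
  phi <- xs_row[2L] / config$tube_radius_um
  list(u = c(1, 0, 0),
       v = c(0, cos(phi), sin(phi)),
       n = c(0, -sin(phi), cos(phi)))
}

.sim_reflect <- function(x, lo, hi) {
  # reflect a coordinate into [lo, hi]
  width <- hi - lo
  x <- (x - lo) %% (2 * width)
  ifelse(x > width, 2 * width - x, x) + lo
}

# place n points in [xlim] x [slim] with minimum spacing (rejection)
.sim_place <- function(n, xlim, slim, min_spacing) {
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  max_tries <- 500L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("cannot place ", n, " cells at min spacing ", min_spacing,
           " um in the configured field; enlarge the field or reduce n_cells")
    cand <- c(runif(1, xlim[1], xlim[2]), runif(1, slim[1], slim[2]))
    if (placed == 0L ||
        min(sqrt(rowSums((pts[seq_len(placed), , drop = FALSE] -
                            matrix(cand, placed, 2L, byrow = TRUE))^2))) >=
        min_spacing) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  pts
}

# random walk with reflecting boundaries; returns frames x 2 matrix
.sim_walk <- function(start, n_frames, sd, xlim, slim) {
  if (sd == 0) {
    return(matrix(rep(start, each = n_frames), n_frames, 2L))
  }
  steps <- matrix(rnorm(2L * (n_frames - 1L), 0, sd), ncol = 2L)
  xs <- apply(rbind(start, steps), 2L, cumsum)
  xs[, 1L] <- .sim_reflect(xs[, 1L], xlim[1], xlim[2])
  xs[, 2L] <- .sim_reflect(xs[, 2L], slim[1], slim[2])
  xs
}

.sim_volume_for <- function(label, n) {
  switch(label,
         stem = runif(n, 50, 110),
         enteroblast = runif(n, 50, 110),
         enteroendocrine = runif(n, 35, 80),
         enterocyte = runif(n, 180, 500))
}

# -- standalone event generators -------------------------------------------

#' Generate one synthetic extrusion event
#'
#' Builds the annotation tables of a single-enterocyte extrusion: a six-sided
#' junctional ring whose area follows an alternating piecewise-linear
#' schedule with `n_pulses` constriction pulses whose amplitudes scale with
#' the current ring area (constriction rates exceed relaxation rates about
#' twofold, driving net closure to 2% of the starting area), basal-plane
#' reference points, and the extruding nucleus' apical-travel schedule (rise
#' from baseline, peak, recoil to a plateau).
#'
#' @param config A [sim_config()].
#' @param start_min Event start time (minutes from movie start).
#' @param closure_min Ring-closure duration in minutes (~4-6 hr in vivo);
#'   must span at least 2 frames.
#' @param n_pulses Number of constriction pulses (>= 1; observed events show
#'   6-12).
#' @param center_xs Unrolled `(x, s)` position of the ring center; defaults
#'   to the field center.
#' @param area0_um2 Initial ring area (default 250).
#' @param peak_um,plateau_um Nuclear travel peak and final plateau heights
#'   (default 18 and 10 um apical of the basal plane).
#' @param event_id,cell_id Identifiers used in the output tables.
#' @param vertex_noise_sd Gaussian jitter added to ring vertices (um,
#'   default 0).
#' @return List with `rings`, `planes` (CSV-schema data.frames), `nucleus`
#'   (data.frame `frame`, `t_min`, `dist_um` plus 3D positions) and `truth`
#'   (pulse schedule, travel onset/peak/recoil).
#' @export
generate_extrusion_event <- function(config, start_min, closure_min, n_pulses,
                                     center_xs = NULL, area0_um2 = 250,
                                     peak_um = 18, plateau_um = 10,
                                     event_id = "ex01", cell_id = "ex01_cell",
                                     vertex_noise_sd = 0) {
  if (n_pulses < 1L) stop("'n_pulses' must be >= 1")
  stopifnot_scalar_num(closure_min, "closure_min", positive = TRUE)
  dt_frame <- config$frame_interval_min
  if (closure_min < 2 * dt_frame)
    stop("closure duration must span at least 2 frames")
  if (is.null(center_xs)) center_xs <- c(config$field_length_um / 2, 0)

  # Alternating piecewise-linear schedule of equal-duration segments. Pulse
  # amplitudes scale with the current ring area (junctional tension scales
  # with ring size): each constriction multiplies the area by f_c and each
  # relaxation by f_r = f_c^(-1/2), i.e. a relaxation recovers half of a
  # constriction on the log scale, so constriction rates always exceed
  # relaxation rates about twofold and the ring closes to 2% of its initial
  # area on net.
  nseg <- 2L * n_pulses - 1L
  seg_dt <- closure_min / nseg
  log_fc <- log(0.02) / (n_pulses - (n_pulses - 1L) / 2)
  kinds <- rep(c("constriction", "relaxation"), length.out = nseg)
  log_steps <- ifelse(kinds == "constriction", log_fc, -log_fc / 2)
  seg_start <- start_min + (seq_len(nseg) - 1L) * seg_dt
  knot_t <- c(seg_start, start_min + closure_min)
  knot_a <- area0_um2 * exp(c(0, cumsum(log_steps)))
  rates <- diff(knot_a) / seg_dt
  area_at <- function(t) approx(knot_t, knot_a, xout = t, rule = 2)$y

  frames <- which(((seq_len(config$n_frames) - 1L) * dt_frame) >= start_min &
                    ((seq_len(config$n_frames) - 1L) * dt_frame) <=
                    start_min + closure_min) - 1L
  if (length(frames) < 3L) stop("closure window covers fewer than 3 frames")
  t_frames <- frames * dt_frame
  areas <- area_at(t_frames)

  fr <- .sim_frame(center_xs, config)
  center3 <- .sim_embed(matrix(center_xs, 1L), config)[1L, ]
  # ring drifts slowly apically during closure
  apical_drift <- 3 * (t_frames - start_min) / closure_min

  ring_rows <- list()
  for (k in seq_along(frames)) {
    rho <- sqrt(2 * max(areas[k], 1e-9) / (3 * sqrt(3)))
    ang <- deg2rad(60 * (0:5) + 10)
    ctr <- center3 + apical_drift[k] * fr$n
    vs <- t(vapply(ang, function(a)
      ctr + rho * (cos(a) * fr$u + sin(a) * fr$v), numeric(3L)))
    if (vertex_noise_sd > 0)
      vs <- vs + matrix(rnorm(18L, 0, vertex_noise_sd), 6L, 3L)
    ring_rows[[k]] <- data.frame(movie_id = config$movie_id,
                                 event_id = event_id, frame = frames[k],
                                 t_min = t_frames[k], vertex_index = 0:5,
                                 x_um = vs[, 1L], y_um = vs[, 2L],
                                 z_um = vs[, 3L], stringsAsFactors = FALSE)
  }
  rings <- do.call(rbind, ring_rows)

  pp <- rbind(center3 + 8 * fr$u,
              center3 - 4 * fr$u + 7 * fr$v,
              center3 - 4 * fr$u - 7 * fr$v)
  planes <- do.call(rbind, lapply(seq_along(frames), function(k)
    data.frame(movie_id = config$movie_id, event_id = event_id,
               frame = frames[k], point_index = 1:3,
               x_um = pp[, 1L], y_um = pp[, 2L], z_um = pp[, 3L],
               stringsAsFactors = FALSE)))

  # nuclear travel: flat 0, rise from 0.35 to 0.65 of closure, recoil to a
  # plateau reached at 0.85 of closure
  t_rise <- start_min + 0.35 * closure_min
  t_peak <- start_min + 0.65 * closure_min
  t_plat <- start_min + 0.85 * closure_min
  all_t <- (seq_len(config$n_frames) - 1L) * dt_frame
  h <- approx(c(0, t_rise, t_peak, t_plat, max(all_t)),
              c(0, 0, peak_um, plateau_um, plateau_um),
              xout = all_t, rule = 2)$y
  nuc3 <- matrix(rep(center3, each = config$n_frames), ncol = 3L) +
    outer(h, fr$n)
  nucleus <- data.frame(frame = seq_len(config$n_frames) - 1L, t_min = all_t,
                        dist_um = h, x_um = nuc3[, 1L], y_um = nuc3[, 2L],
                        z_um = nuc3[, 3L], stringsAsFactors = FALSE)

  truth <- list(event_id = event_id, cell_id = cell_id,
                n_pulses = n_pulses, area0_um2 = area0_um2,
                segments = data.frame(kind = kinds, start_min = seg_start,
                                      end_min = seg_start + seg_dt,
                                      rate_um2_min = rates,
                                      stringsAsFactors = FALSE),
                final_area_um2 = knot_a[length(knot_a)],
                travel = list(rise_min = t_rise, peak_min = t_peak,
                              peak_um = peak_um,
                              recoil_um = peak_um - plateau_um))
  list(rings = rings, planes = planes, nucleus = nucleus, truth = truth)
}

#' Generate one synthetic mitosis
#'
#' Places spindle poles so that the per-frame horizontal-vertical and
#' longitudinal-circumferential angles equal the requested schedule exactly
#' on the local tangent plane of the tube, and creates two daughter tracks
#' at decondensation, separated along the final spindle direction.
#'
#' @param config A [sim_config()].
#' @param t_condense_min Start of mitosis (nuclear condensation), minutes.
#' @param duration_min Mitosis duration (30-60 min in vivo); must be at
#'   least one frame interval and fit in the movie.
#' @param angle_schedule Matrix / data.frame with columns `hv` and `lc`
#'   (degrees in `[0, 90]`), one row per mitotic frame, or NULL for random
#'   horizontally-biased angles.
#' @param mother_xs Unrolled `(x, s)` mother position (default field
#'   center).
#' @param spindle_um Pole-to-pole spindle length (default 6).
#' @param daughter_sep_um Daughter separation at birth (default 5).
#' @param cell_id Mother cell id used in the record.
#' @return A `mitosis_record` list: condensation/decondensation times,
#'   mitotic `frames`, per-frame `poles` (list of 2 x 3 matrices),
#'   `plane_points`, the scheduled `angles`, `axis_long`, and `daughters`
#'   (birth frame plus 2 x 3 positions).
#' @export
generate_mitosis_event <- function(config, t_condense_min, duration_min,
                                   angle_schedule = NULL, mother_xs = NULL,
                                   spindle_um = 6, daughter_sep_um = 5,
                                   cell_id = "mit01_cell") {
  dt <- config$frame_interval_min
  span <- (config$n_frames - 1L) * dt
  if (duration_min < dt || t_condense_min + duration_min > span)
    stop("mitosis duration must lie within [frame_interval, movie span]")
  if (is.null(mother_xs)) mother_xs <- c(config$field_length_um / 2, 0)
  all_t <- (seq_len(config$n_frames) - 1L) * dt
  frames <- which(all_t >= t_condense_min &
                    all_t <= t_condense_min + duration_min) - 1L
  k <- length(frames)
  if (is.null(angle_schedule)) {
    angle_schedule <- cbind(hv = pmin(abs(rnorm(k, 0, 25)), 90),
                            lc = runif(k, 0, 90))
  }
  angle_schedule <- as.matrix(angle_schedule)
  colnames(angle_schedule) <- c("hv", "lc")
  if (nrow(angle_schedule) != k)
    stop("angle schedule has ", nrow(angle_schedule), " rows but the mitosis",
         " spans ", k, " frames")
  if (any(angle_schedule < 0) || any(angle_schedule > 90))
    stop("angles must lie in [0, 90] degrees")

  fr <- .sim_frame(mother_xs, config)
  ctr <- .sim_embed(matrix(mother_xs, 1L), config)[1L, ]
  dir_at <- function(hv_deg, lc_deg) {
    hv <- deg2rad(hv_deg); lc <- deg2rad(lc_deg)
    cos(hv) * (cos(lc) * fr$u + sin(lc) * fr$v) + sin(hv) * fr$n
  }
  poles <- lapply(seq_len(k), function(i) {
    d <- dir_at(angle_schedule[i, 1L], angle_schedule[i, 2L])
    rbind(ctr + (spindle_um / 2) * d, ctr - (spindle_um / 2) * d)
  })
  plane_points <- rbind(ctr + 8 * fr$u,
                        ctr - 4 * fr$u + 7 * fr$v,
                        ctr - 4 * fr$u - 7 * fr$v)
  d_final <- dir_at(angle_schedule[k, 1L], angle_schedule[k, 2L])
  daughters <- rbind(ctr + (daughter_sep_um / 2) * d_final,
                     ctr - (daughter_sep_um / 2) * d_final)
  structure(list(cell_id = cell_id,
                 t_condense_min = t_condense_min,
                 t_decondense_min = t_condense_min + duration_min,
                 frames = frames, times_min = all_t[frames + 1L],
                 poles = poles, plane_points = plane_points,
                 angles = angle_schedule, axis_long = fr$u,
                 normal = fr$n,
                 mother_position = ctr,
                 daughters = list(birth_frame = max(frames) + 1L,
                                  positions = daughters)),
            class = "mitosis_record")
}
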