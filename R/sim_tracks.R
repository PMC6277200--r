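#' Generate a synthetic tracked-nuclei movie with ground truth
#'
#' Produces a track table in the export schema of the imaging workflow (one
#' row per living cell per frame) plus a complete ground-truth record. Cells
#' live on the cylindrical tube surface and perform a bounded random walk in
#' unrolled surface coordinates; type labels are drawn at the configured
#' fractions (exact quotas by default); enterocyte nuclear volumes exceed
#' 113 um^3 while stem/enteroblast/enteroendocrine volumes stay at or below
#' it; and raw channel intensities are constructed so that per-movie
#' maximum-normalized GFP:RFP ratios of stem cells cluster at the low mode
#' and enteroblasts at the high mode (exactly equal to the scheduled ratios
#' at zero intensity noise, thanks to per-movie anchor nuclei).
#'
#' Scheduled events in the config:
#' * `mitoses`: lists with `t_condense_min`, `duration_min`, optional
#'   `angles` (see [generate_mitosis_event()]) and optional `cell` index.
#' * `extrusions`: lists with `start_min`, `closure_min`, `n_pulses` and
#'   optional extras of [generate_extrusion_event()].
#' * `transitions`: lists with `t_start_min`, optional `baseline`,
#'   `final`; the cell's ratio stays flat at the baseline and then ramps
#'   linearly, crossing the 0.17 fate threshold at a recorded time.
#' * `sibling_pairs`: lists with `t_birth_min` and `states` (character
#'   vector of per-frame contact states, recycled to the movie end).
#' * `collisions`: lists with `t_start_min`, `t_end_min`; a bright mature
#'   enteroblast approaches the target cell to within 3 um over the window.
#'
#' A cell can take part in at most one event; overlapping schedules are
#' rejected.
#'
#' @param config A [sim_config()].
#' @return List with `tracks` (data.frame in the track CSV schema, including
#'   `label`), `rings`/`planes` (extrusion annotation tables or NULL),
#'   `truth` (cells, per-frame true ratios, and per-event records), and the
#'   `config`.
#' @export
generate_tracks <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  set.seed(config$rng_seed)
  n <- config$n_cells
  nf <- config$n_frames
  dt <- config$frame_interval_min
  all_t <- (seq_len(nf) - 1L) * dt
  span <- max(all_t)
  R <- config$tube_radius_um
  xlim <- c(10, config$field_length_um - 10)
  slim <- c(-1, 1) * R * config$band_half_rad

  # -- type labels ----------------------------------------------------------
  if (config$type_assignment == "quota") {
    q <- c(stem = round(config$stem_fraction * n),
           enteroblast = round(config$eb_fraction * n),
           enteroendocrine = round(config$ee_fraction * n))
    while (n - sum(q) < 0) q[which.max(q)] <- q[which.max(q)] - 1L
    labels <- sample(rep(c(names(q), "enterocyte"), c(q, n - sum(q))))
  } else {
    p <- c(config$stem_fraction, config$eb_fraction, config$ee_fraction)
    labels <- sample(c("stem", "enteroblast", "enteroendocrine", "enterocyte"),
                     n, replace = TRUE, prob = c(p, 1 - sum(p)))
  }

  volumes <- numeric(n)
  for (lb in unique(labels)) {
    sel <- labels == lb
    volumes[sel] <- .sim_volume_for(lb, sum(sel))
  }

  xs0 <- .sim_place(n, xlim, slim, config$min_spacing_um)

  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cells[[i]] <- list(id = sprintf("c%03d", i), label = labels[i],
                       f0 = 0L, f1 = nf - 1L,
                       xs = .sim_walk(xs0[i, ], nf, config$motion_sd_um,
                                      xlim, slim),
                       volume = volumes[i], pos_override = NULL,
                       ratio_kind = "base")
  }

  # -- event cell assignment ------------------------------------------------
  used <- integer(0)
  pick_cell <- function(lbl) {
    cand <- setdiff(which(labels == lbl), used)
    if (!length(cand))
      stop("no unused '", lbl, "' cell available for a scheduled event")
    cand[1L]
  }
  truth_events <- list(mitoses = list(), extrusions = list(),
                       transitions = list(), sibling_pairs = list(),
                       collisions = list())
  rings <- NULL; planes <- NULL
  extra <- list()  # daughters, siblings, collision neighbors
  n_extra <- 0L
  add_extra <- function(cell) {
    n_extra <<- n_extra + 1L
    cell$id <- sprintf("x%03d", n_extra)
    extra[[n_extra]] <<- cell
    cell$id
  }

  for (ev in config$mitoses) {
    i <- if (!is.null(ev$cell)) ev$cell else pick_cell("stem")
    if (i %in% used) stop("cell ", i, " is scheduled in more than one event")
    used <- c(used, i)
    f_start <- which(all_t >= ev$t_condense_min)[1L] - 1L
    rec <- generate_mitosis_event(config, ev$t_condense_min, ev$duration_min,
                                  angle_schedule = ev$angles,
                                  mother_xs = cells[[i]]$xs[f_start + 1L, ],
                                  cell_id = cells[[i]]$id)
    # mother pauses in place during mitosis and ends at decondensation
    cells[[i]]$xs[rec$frames + 1L, ] <-
      matrix(cells[[i]]$xs[f_start + 1L, ], length(rec$frames), 2L,
             byrow = TRUE)
    cells[[i]]$f1 <- max(rec$frames)
    fb <- rec$daughters$birth_frame
    if (fb <= nf - 1L) {
      fr <- .sim_frame(cells[[i]]$xs[f_start + 1L, ], config)
      for (dix in 1:2) {
        dpos3 <- rec$daughters$positions[dix, ]
        rel <- dpos3 - rec$mother_position
        start_xs <- cells[[i]]$xs[f_start + 1L, ] +
          c(sum(rel * fr$u), sum(rel * fr$v))
        walk <- .sim_walk(start_xs, nf - fb, config$motion_sd_um, xlim, slim)
        did <- add_extra(list(label = "stem", f0 = fb, f1 = nf - 1L,
                              xs = walk, volume = runif(1, 50, 110),
                              pos_override = NULL, ratio_kind = "base"))
        if (dix == 1L) rec$daughter_ids <- did else
          rec$daughter_ids <- c(rec$daughter_ids, did)
      }
    }
    truth_events$mitoses[[length(truth_events$mitoses) + 1L]] <- rec
  }

  for (ev in config$extrusions) {
    i <- if (!is.null(ev$cell)) ev$cell else pick_cell("enterocyte")
    if (i %in% used) stop("cell ", i, " is scheduled in more than one event")
    used <- c(used, i)
    f_start <- which(all_t >= ev$start_min)[1L] - 1L
    eid <- sprintf("ex%02d", length(truth_events$extrusions) + 1L)
    exev <- generate_extrusion_event(
      config, ev$start_min, ev$closure_min, ev$n_pulses,
      center_xs = cells[[i]]$xs[f_start + 1L, ],
      area0_um2 = ev$area0_um2 %||% 250,
      vertex_noise_sd = ev$vertex_noise_sd %||% 0,
      event_id = eid, cell_id = cells[[i]]$id)
    cells[[i]]$pos_override <-
      as.matrix(exev$nucleus[, c("x_um", "y_um", "z_um")])
    rings <- rbind(rings, exev$rings)
    planes <- rbind(planes, exev$planes)
    truth_events$extrusions[[length(truth_events$extrusions) + 1L]] <-
      exev$truth
  }

  for (ev in config$transitions) {
    i <- if (!is.null(ev$cell)) ev$cell else pick_cell("stem")
    if (i %in% used) stop("cell ", i, " is scheduled in more than one event")
    used <- c(used, i)
    baseline <- ev$baseline %||% runif(1, 0.02, 0.08)
    final <- ev$final %||% runif(1, 0.35, 0.55)
    if (ev$t_start_min >= span) stop("transition starts after the movie ends")
    slope <- (final - baseline) / (span - ev$t_start_min)
    cells[[i]]$ratio_kind <- "transition"
    cells[[i]]$ratio_sched <- pmin(
      baseline + pmax(all_t - ev$t_start_min, 0) * slope, 1.0)
    truth_events$transitions[[length(truth_events$transitions) + 1L]] <-
      list(cell_id = cells[[i]]$id, t_start_min = ev$t_start_min,
           baseline = baseline, final = final, slope_per_min = slope,
           t_cross_017_min = ev$t_start_min + (0.17 - baseline) / slope)
  }

  for (ev in config$collisions) {
    i <- if (!is.null(ev$cell)) ev$cell else pick_cell("stem")
    if (i %in% used) stop("cell ", i, " is scheduled in more than one event")
    used <- c(used, i)
    near <- all_t >= ev$t_start_min & all_t <= ev$t_end_min
    off <- ifelse(near, 3, 18)
    nb_xs <- cells[[i]]$xs
    nb_xs[, 2L] <- nb_xs[, 2L] + off
    nid <- add_extra(list(label = "enteroblast", f0 = 0L, f1 = nf - 1L,
                          xs = nb_xs, volume = runif(1, 50, 110),
                          pos_override = NULL, ratio_kind = "fixed",
                          ratio_sched = rep(0.85, nf)))
    truth_events$collisions[[length(truth_events$collisions) + 1L]] <-
      list(target_id = cells[[i]]$id, neighbor_id = nid,
           t_start_min = ev$t_start_min, t_end_min = ev$t_end_min,
           frames = which(near) - 1L)
  }

  for (ev in config$sibling_pairs) {
    fb <- which(all_t >= ev$t_birth_min)[1L] - 1L
    if (is.na(fb) || fb > nf - 2L) stop("sibling birth too late in the movie")
    n_after <- nf - fb
    states <- rep(ev$states %||% "contact", length.out = n_after)
    bad <- setdiff(states, c("contact", "indeterminate", "separated"))
    if (length(bad)) stop("unknown contact state(s): ", paste(bad, collapse = ", "))
    anchor <- c(runif(1, xlim[1], xlim[2]), runif(1, slim[1], slim[2]))
    walk1 <- .sim_walk(anchor, n_after, config$motion_sd_um, xlim, slim)
    dist <- c(contact = 4, indeterminate = 10, separated = 20)[states]
    walk2 <- walk1
    walk2[, 2L] <- walk2[, 2L] + dist
    id1 <- add_extra(list(label = "stem", f0 = fb, f1 = nf - 1L, xs = walk1,
                          volume = runif(1, 50, 110), pos_override = NULL,
                          ratio_kind = "base"))
    id2 <- add_extra(list(label = "stem", f0 = fb, f1 = nf - 1L, xs = walk2,
                          volume = runif(1, 50, 110), pos_override = NULL,
                          ratio_kind = "base"))
    truth_events$sibling_pairs[[length(truth_events$sibling_pairs) + 1L]] <-
      list(cell_id1 = id1, cell_id2 = id2, birth_frame = fb,
           t_birth_min = all_t[fb + 1L], states = states)
  }

  cells <- c(cells, extra)
  nc <- length(cells)
  labels_all <- vapply(cells, `[[`, character(1L), "label")

  # -- scheduled GFP:RFP ratios --------------------------------------------
  m <- config$ratio_modes; s <- config$ratio_mode_sds
  eb_idx <- which(labels_all == "enteroblast" &
                    vapply(cells, function(c.) c.$ratio_kind == "base",
                           logical(1L)))
  calibrator <- if (length(eb_idx)) eb_idx[1L] else NA_integer_
  r_cal <- NA_real_
  ratio <- matrix(0, nc, nf)
  for (i in seq_len(nc)) {
    ci <- cells[[i]]
    if (ci$ratio_kind %in% c("transition", "fixed")) {
      ratio[i, ] <- ci$ratio_sched
    } else if (!is.na(calibrator) && i == calibrator) {
      r_cal <- runif(1, 1.2, 1.6)
      ratio[i, ] <- r_cal
    } else if (ci$label == "stem") {
      # mode width split between cell-to-cell and temporal variation
      base <- .rtrunc(1, m[1], s[1] / sqrt(2), 0, 0.10)
      ratio[i, ] <- pmin(pmax(base + rnorm(nf, 0, s[1] / sqrt(2)), 0), 0.12)
    } else if (ci$label == "enteroblast") {
      base <- .rtrunc(1, m[2], s[2] / sqrt(2), 0.25, 1.0)
      ratio[i, ] <- pmin(pmax(base + rnorm(nf, 0, s[2] / sqrt(2)), 0.2), 1.0)
    } else {
      ratio[i, ] <- 0
    }
  }

  # -- amplitudes and anchors ----------------------------------------------
  a_rfp <- runif(nc, 0.55, 0.95)
  ec_idx <- which(labels_all == "enterocyte")
  anchor <- if (length(ec_idx)) ec_idx[1L] else
    setdiff(seq_len(nc), calibrator)[1L]
  a_rfp[anchor] <- 1
  if (!is.na(calibrator)) a_rfp[calibrator] <- 1 / r_cal
  esg <- labels_all %in% c("stem", "enteroblast")
  a_cfp <- ifelse(esg, runif(nc, 0.45, 0.9), 0)

  gains <- config$gains %||%
    setNames(runif(3, 800, 1600), c("cfp", "gfp", "rfp"))

  # -- assemble table -------------------------------------------------------
  rows <- vector("list", nc)
  for (i in seq_len(nc)) {
    ci <- cells[[i]]
    fs <- ci$f0:ci$f1
    pos <- if (!is.null(ci$pos_override)) ci$pos_override[fs + 1L, , drop = FALSE]
      else .sim_embed(ci$xs[(fs - ci$f0) + 1L, , drop = FALSE], config)
    nfr <- length(fs)
    noise <- function(gain) if (config$intensity_noise_sd > 0)
      rnorm(nfr, 0, config$intensity_noise_sd * gain) else 0
    rows[[i]] <- data.frame(
      movie_id = config$movie_id, cell_id = ci$id, frame = fs,
      t_min = all_t[fs + 1L],
      x_um = pos[, 1L], y_um = pos[, 2L], z_um = pos[, 3L],
      volume_um3 = ci$volume,
      cfp_raw = pmax(a_cfp[i] * gains[["cfp"]] + noise(gains[["cfp"]]), 0),
      gfp_raw = pmax(ratio[i, fs + 1L] * a_rfp[i] * gains[["gfp"]] +
                       noise(gains[["gfp"]]), 0),
      rfp_raw = pmax(a_rfp[i] * gains[["rfp"]] + noise(gains[["rfp"]]), 0),
      label = ci$label, stringsAsFactors = FALSE)
  }
  tracks <- do.call(rbind, rows)
  rownames(tracks) <- NULL

  ratio_true <- do.call(rbind, lapply(seq_len(nc), function(i) {
    ci <- cells[[i]]
    fs <- ci$f0:ci$f1
    data.frame(cell_id = ci$id, frame = fs, ratio_true = ratio[i, fs + 1L],
               stringsAsFactors = FALSE)
  }))

  # mitosis records summarized for benchmark / index use
  mito_df <- if (length(truth_events$mitoses)) {
    do.call(rbind, lapply(truth_events$mitoses, function(r)
      data.frame(movie_id = config$movie_id, cell_id = r$cell_id,
                 t_condense_min = r$t_condense_min,
                 t_decondense_min = r$t_decondense_min,
                 stringsAsFactors = FALSE)))
  } else NULL

  truth <- list(
    cells = data.frame(cell_id = vapply(cells, `[[`, character(1L), "id"),
                       label = labels_all,
                       volume_um3 = vapply(cells, `[[`, numeric(1L), "volume"),
                       first_frame = vapply(cells, `[[`, integer(1L), "f0"),
                       last_frame = vapply(cells, `[[`, integer(1L), "f1"),
                       stringsAsFactors = FALSE),
    ratios = ratio_true,
    gains = as.list(gains),
    events = truth_events,
    mitosis_table = mito_df)

  list(tracks = tracks, rings = rings, planes = planes, truth = truth,
       config = config)
}

#' Render a track table as a multichannel image volume
#'
#' Each nucleus is rendered as a sphere of its ground-truth volume with a
#' Gaussian-blurred edge (default) or as a 3D Gaussian blob, at the per-cell
#' raw channel intensity as peak amplitude; channels are CFP, GFP, RFP.
#' Additive Gaussian noise of configurable SD is applied per voxel. With the
#' default profile, thresholding midway up a nucleus' edge recovers its
#' volume, so segmentation-based typing is testable end to end.
#'
#' @param tracks Track table rows to render (any subset of frames).
#' @param config A [sim_config()] (supplies voxel size).
#' @param frames Frames to render (default: all frames present in `tracks`).
#' @param noise_sd Additive intensity noise SD (absolute units; default 0).
#' @param margin_um Padding around the cell bounding box (default 8).
#' @param origin_um,dims_zyx Optional fixed field `(z, y, x)`: physical
#'   origin and voxel counts. Centroids outside the field are an error
#'   listing the offending cells.
#' @param profile `"ball"` (blurred sphere, default) or `"gaussian"`.
#' @param edge_um Edge width of the ball profile (default 1).
#' @return List with `stack` (array `(t, c, z, y, x)`), `frames`,
#'   `origin_um`, `voxel_size_um` and `channel_names`.
#' @export
render_volume <- function(tracks, config, frames = NULL, noise_sd = 0,
                          margin_um = 8, origin_um = NULL, dims_zyx = NULL,
                          profile = c("ball", "gaussian"), edge_um = 1) {
  profile <- match.arg(profile)
  vox <- config$voxel_size_um  # (z, y, x)
  channel_names <- c("cfp", "gfp", "rfp")
  if (is.null(frames)) frames <- sort(unique(tracks$frame))
  if (nrow(tracks) == 0L) {
    dims_zyx <- dims_zyx %||% c(8L, 32L, 32L)
    if (!length(frames)) frames <- 0L
    stack <- array(0, c(length(frames), 3L, dims_zyx))
    if (noise_sd > 0)
      stack <- pmax(stack + array(rnorm(length(stack), 0, noise_sd),
                                  dim(stack)), 0)
    return(list(stack = stack, frames = frames,
                origin_um = origin_um %||% c(0, 0, 0),
                voxel_size_um = vox, channel_names = channel_names))
  }
  tracks <- tracks[tracks$frame %in% frames, , drop = FALSE]
  rad_all <- (3 * tracks$volume_um3 / (4 * pi))^(1 / 3)
  pad <- max(rad_all) + edge_um
  if (is.null(origin_um)) {
    origin_um <- c(min(tracks$z_um) - pad - margin_um,
                   min(tracks$y_um) - pad - margin_um,
                   min(tracks$x_um) - pad - margin_um)
  }
  if (is.null(dims_zyx)) {
    hi <- c(max(tracks$z_um), max(tracks$y_um), max(tracks$x_um)) +
      pad + margin_um
    dims_zyx <- as.integer(ceiling((hi - origin_um) / vox))
  }
  # bounds check
  lo_ok <- tracks$z_um >= origin_um[1] & tracks$y_um >= origin_um[2] &
    tracks$x_um >= origin_um[3]
  hi_um <- origin_um + dims_zyx * vox
  hi_ok <- tracks$z_um <= hi_um[1] & tracks$y_um <= hi_um[2] &
    tracks$x_um <= hi_um[3]
  if (any(!(lo_ok & hi_ok)))
    stop("centroid(s) outside the rendering field for cell(s): ",
         paste(unique(tracks$cell_id[!(lo_ok & hi_ok)]), collapse = ", "))

  stack <- array(0, c(length(frames), 3L, dims_zyx))
  for (fi in seq_along(frames)) {
    sub <- tracks[tracks$frame == frames[fi], , drop = FALSE]
    vols <- lapply(1:3, function(ch) array(0, dims_zyx))
    for (r in seq_len(nrow(sub))) {
      rad <- (3 * sub$volume_um3[r] / (4 * pi))^(1 / 3)
      ctr <- c(sub$z_um[r], sub$y_um[r], sub$x_um[r])
      rmax <- if (profile == "ball") rad + edge_um / 2 else
        3 * rad / sqrt(2 * log(2))
      rng <- lapply(1:3, function(ax) {
        lo <- max(1L, as.integer(ceiling((ctr[ax] - rmax - origin_um[ax]) /
                                           vox[ax] + 0.5)))
        hi <- min(dims_zyx[ax], as.integer(floor((ctr[ax] + rmax -
                                                    origin_um[ax]) /
                                                   vox[ax] + 0.5)))
        if (lo > hi) integer(0) else lo:hi
      })
      if (!all(lengths(rng) > 0L)) next
      cz <- origin_um[1] + (rng[[1]] - 0.5) * vox[1] - ctr[1]
      cy <- origin_um[2] + (rng[[2]] - 0.5) * vox[2] - ctr[2]
      cx <- origin_um[3] + (rng[[3]] - 0.5) * vox[3] - ctr[3]
      d2 <- outer(outer(cz^2, cy^2, "+"), cx^2, "+")
      rr <- sqrt(d2)
      b <- if (profile == "ball") {
        ifelse(rr <= rad - edge_um / 2, 1,
               ifelse(rr >= rad + edge_um / 2, 0,
                      0.5 * (1 + cos(pi * (rr - rad + edge_um / 2) /
                                       edge_um))))
      } else {
        sigma <- rad / sqrt(2 * log(2))
        exp(-d2 / (2 * sigma^2))
      }
      amps <- c(sub$cfp_raw[r], sub$gfp_raw[r], sub$rfp_raw[r])
      idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      bv <- as.vector(b)  # expand.grid order matches array element order
      for (ch in 1:3) {
        if (amps[ch] <= 0) next
        vols[[ch]][idx] <- vols[[ch]][idx] + amps[ch] * bv
      }
    }
    for (ch in 1:3) {
      v <- vols[[ch]]
      if (noise_sd > 0)
        v <- pmax(v + array(rnorm(length(v), 0, noise_sd), dim(v)), 0)
      stack[fi, ch, , , ] <- v
    }
  }
  list(stack = stack, frames = frames, origin_um = origin_um,
       voxel_size_um = vox, channel_names = channel_names)
}
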