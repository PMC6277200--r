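#' Fit a basal reference plane through three surface points
#'
#' The basal epithelial surface under an extruding cell or a mitotic spindle
#' is annotated by three reference points. The plane through them is
#' summarised by a unit normal and one of the points; the normal is the
#' normalized cross product of the two in-plane edge vectors. By convention
#' the normal points to the apical side (towards the gut lumen, away from the
#' objective-side tissue); pass `apical_hint` to orient it.
#'
#' @param p1,p2,p3 Numeric length-3 points in micrometres.
#' @param apical_hint Optional length-3 vector with a positive component along
#'   the apical direction; the normal is flipped to satisfy
#'   `dot(normal, apical_hint) > 0`.
#' @param tol Minimum triangle area (um^2) below which the points are treated
#'   as collinear.
#' @return An object of class `basal_plane`: a list with `normal` (unit
#'   length), `point` (the first reference point) and `points` (3 x 3 matrix).
#' @examples
#' pl <- fit_basal_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' pl$normal
#' @export
fit_basal_plane <- function(p1, p2, p3, apical_hint = NULL, tol = 1e-9) {
  p1 <- as_point3(p1, "p1"); p2 <- as_point3(p2, "p2"); p3 <- as_point3(p3, "p3")
  cr <- cross3(p2 - p1, p3 - p1)
  area <- vec_norm(cr) / 2
  if (area < tol)
    stop("basal plane reference points are collinear (triangle area below tolerance)")
  normal <- cr / (2 * area)
  if (!is.null(apical_hint)) {
    apical_hint <- as_point3(apical_hint, "apical_hint")
    if (sum(normal * apical_hint) < 0) normal <- -normal
  }
  structure(list(normal = normal, point = p1, points = rbind(p1, p2, p3)),
            class = "basal_plane")
}

#' @export
print.basal_plane <- function(x, ...) {
  cat("basal plane: normal (",
      paste(sprintf("%.4f", x$normal), collapse = ", "),
      "), through (", paste(sprintf("%.2f", x$point), collapse = ", "), ") um\n",
      sep = "")
  invisible(x)
}

#' Cross-sectional area of a junctional ring
#'
#' The polygon outlined by the ring vertices is triangulated as a fan around
#' its centroid: the area of each component triangle is half the norm of the
#' cross product of the two vectors from the centroid to adjacent vertices,
#' and the ring area is their sum. The result is exact for planar convex
#' polygons and remains well defined for slightly non-planar rings.
#'
#' @param vertices An n x 3 matrix of ordered ring vertices (um), n >= 3.
#'   The winding order does not affect the result.
#' @return Ring area in um^2 (non-negative).
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' ring_area(sq) # 1
#' @export
ring_area <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L) stop("'vertices' must be an n x 3 matrix")
  n <- nrow(vertices)
  if (n < 3L) stop("a ring needs at least 3 vertices")
  if (any(!is.finite(vertices))) stop("ring vertices must be finite")
  ctr <- colMeans(vertices)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    total <- total + vec_norm(cross3(vertices[i, ] - ctr, vertices[j, ] - ctr)) / 2
  }
  total
}

#' Project a ring onto the basal plane ('footprint')
#'
#' Each vertex is orthogonally projected onto the basal plane and expressed in
#' a fixed 2D in-plane basis (first basis vector along the plane's first edge,
#' second completing a right-handed frame with the normal). Vertex order is
#' preserved, so footprints from successive frames can be overlaid.
#'
#' @param vertices n x 3 matrix of ring vertices (um).
#' @param plane A [fit_basal_plane()] object.
#' @return n x 2 matrix of in-plane coordinates (um), with attribute
#'   `"basis"` (2 x 3 matrix of the in-plane basis vectors) and `"origin"`.
#' @export
ring_footprint <- function(vertices, plane) {
  if (!inherits(plane, "basal_plane")) stop("'plane' must be a basal_plane object")
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L) stop("'vertices' must be an n x 3 matrix")
  e1 <- unit_vec(plane$points[2, ] - plane$points[1, ])
  e2 <- cross3(plane$normal, e1)
  rel <- sweep(vertices, 2, plane$point)
  out <- cbind(u = rel %*% e1, v = rel %*% e2)
  colnames(out) <- c("u", "v")
  attr(out, "basis") <- rbind(e1 = e1, e2 = e2)
  attr(out, "origin") <- plane$point
  out
}

#' Signed orthogonal distance from a point to the basal plane
#'
#' Computed as the dot product of the plane's unit normal with the vector from
#' the reference point to the query point. Positive values are on the apical
#' side (the side the normal points to).
#'
#' @param point A length-3 point, or an n x 3 matrix of points (um).
#' @param plane A [fit_basal_plane()] object.
#' @return Signed distance(s) in um.
#' @export
plane_distance <- function(point, plane) {
  if (!inherits(plane, "basal_plane")) stop("'plane' must be a basal_plane object")
  if (is.matrix(point)) {
    if (ncol(point) != 3L) stop("'point' matrix must have 3 columns")
    as.numeric(sweep(point, 2, plane$point) %*% plane$normal)
  } else {
    sum(plane$normal * (as_point3(point) - plane$point))
  }
}

#' Decompose a ring-area series into ratchet pulses
#'
#' Junctional-ring closure during enterocyte extrusion is ratcheted: pulses of
#' constriction alternate with pulses of relaxation/stabilization, with
#' constriction rates exceeding relaxation rates so the ring closes on net.
#' Detection runs on the log-area series (when all areas are positive):
#' annotation noise and pulse amplitudes both scale with ring size, so the
#' log scale makes the decomposition scale-invariant, and monotone
#' transforms preserve segment boundaries exactly. The (log) series is
#' smoothed by a centered moving average and decomposed at its turning
#' points, found with amplitude hysteresis: a direction reversal is
#' committed only when the smoothed series retraces by more than
#' `hysteresis` from its running extremum, which suppresses noise blips
#' while keeping noiseless kinks exact. Boundaries are then optionally
#' snapped to the local extremum of the *raw* series near each smoothed
#' turning point (a constriction-to-relaxation boundary is a local area
#' minimum, the converse a maximum), removing the smoothing lag. Each
#' segment's mean rate dA/dt is computed on the raw series; segments with
#' rate below `-epsilon` are `constriction`, the rest `relaxation`
#' (stabilization counts as relaxation), and adjacent same-kind segments are
#' merged so kinds alternate.
#'
#' @param t_min Strictly increasing times in minutes (>= 3 points).
#' @param area_um2 Ring areas in um^2, same length as `t_min`.
#' @param window Centered moving-average window in frames (default 1, no
#'   smoothing). Ratchet pulses at 5-15 min sampling span only 2-6 frames,
#'   which a moving average attenuates below the hysteresis; noise
#'   robustness comes from the hysteresis itself, so smoothing is off by
#'   default and available for oversampled series.
#' @param epsilon Rate dead-band on the detection scale (log-area per
#'   minute by default). Default 5% of the maximum absolute per-interval
#'   detection-scale rate; segment rates in `[-epsilon, epsilon]` count as
#'   stabilization and are grouped with relaxation.
#' @param hysteresis Minimum retracement, on the detection scale, committing
#'   a direction reversal. On the default log-area scale this is 0.12, i.e.
#'   a relaxation (or constriction) must move the ring area by at least
#'   ~13% to count as a pulse -- well below the severalfold area changes of
#'   observed pulses, and several standard deviations above smoothed
#'   annotation noise of a few percent. When detection falls back to the
#'   identity scale (non-positive areas) the default is 5% of the series
#'   range.
#' @param refine Snap segment boundaries to raw-series extrema (default TRUE).
#' @return A data.frame of segments with columns `kind`
#'   (`"constriction"`/`"relaxation"`), `start_min`, `end_min`,
#'   `mean_rate_um2_min` (signed, from the raw series), and
#'   `area_change_um2`. Attribute `"summary"` holds cumulative time and mean
#'   rate per kind.
#' @examples
#' t <- seq(0, 100, by = 10)
#' a <- 100 - t              # steady constriction
#' detect_pulses(t, a)
#' @export
detect_pulses <- function(t_min, area_um2, window = 1L, epsilon = NULL,
                          hysteresis = NULL, refine = TRUE) {
  t_min <- as.numeric(t_min); area_um2 <- as.numeric(area_um2)
  n <- length(t_min)
  if (n < 3L) stop("need at least 3 points to detect pulses")
  if (length(area_um2) != n) stop("'t_min' and 'area_um2' lengths differ")
  if (any(diff(t_min) <= 0)) stop("'t_min' must be strictly increasing")
  window <- as.integer(window)
  if (window > n) stop("smoothing window larger than series")

  y <- if (all(area_um2 > 0)) log(area_um2) else area_um2
  sm <- moving_average(y, window)
  if (is.null(epsilon)) epsilon <- 0.05 * max(abs(diff(sm) / diff(t_min)))
  if (is.null(hysteresis)) {
    hysteresis <- if (all(area_um2 > 0)) 0.12 else
      0.05 * diff(range(area_um2))
  }

  # turning points with amplitude hysteresis on the smoothed series
  turns <- integer(0)       # frame index of each committed extremum
  turn_dir <- integer(0)    # +1: local max committed, -1: local min
  dir <- 0L
  min_i <- 1L; max_i <- 1L
  for (i in 2:n) {
    if (sm[i] < sm[min_i]) min_i <- i
    if (sm[i] > sm[max_i]) max_i <- i
    if (dir <= 0L && sm[i] - sm[min_i] > hysteresis) {
      turns <- c(turns, min_i); turn_dir <- c(turn_dir, -1L)
      dir <- 1L; max_i <- i
    } else if (dir >= 0L && sm[max_i] - sm[i] > hysteresis) {
      turns <- c(turns, max_i); turn_dir <- c(turn_dir, 1L)
      dir <- -1L; min_i <- i
    }
  }
  keep <- turns > 1L & turns < n
  turns <- turns[keep]; turn_dir <- turn_dir[keep]

  bounds <- c(1L, turns, n)
  if (refine && length(turns)) {
    for (b in seq_along(turns)) {
      lo <- max(bounds[b] + 1L, bounds[b + 1L] - window)
      hi <- min(bounds[b + 2L] - 1L, bounds[b + 1L] + window)
      if (lo > hi) next
      idx <- lo:hi
      bounds[b + 1L] <- if (turn_dir[b] < 0L)
        idx[which.min(area_um2[idx])] else idx[which.max(area_um2[idx])]
    }
  }

  nseg <- length(bounds) - 1L
  seg <- data.frame(
    start_min = t_min[bounds[seq_len(nseg)]],
    end_min = t_min[bounds[seq_len(nseg) + 1L]],
    stringsAsFactors = FALSE
  )
  seg$area_change_um2 <- area_um2[bounds[seq_len(nseg) + 1L]] -
    area_um2[bounds[seq_len(nseg)]]
  seg$mean_rate_um2_min <- seg$area_change_um2 / (seg$end_min - seg$start_min)
  det_rate <- (y[bounds[seq_len(nseg) + 1L]] - y[bounds[seq_len(nseg)]]) /
    (seg$end_min - seg$start_min)
  seg <- cbind(kind = ifelse(det_rate < -epsilon, "constriction",
                             "relaxation"), seg, stringsAsFactors = FALSE)

  # merge adjacent same-kind segments so kinds alternate
  i <- 1L
  while (i < nrow(seg)) {
    if (seg$kind[i] == seg$kind[i + 1L]) {
      seg$end_min[i] <- seg$end_min[i + 1L]
      seg$area_change_um2[i] <- seg$area_change_um2[i] +
        seg$area_change_um2[i + 1L]
      seg$mean_rate_um2_min[i] <- seg$area_change_um2[i] /
        (seg$end_min[i] - seg$start_min[i])
      seg <- seg[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(seg) <- NULL

  smry <- lapply(split(seg, seg$kind), function(s) {
    list(total_min = sum(s$end_min - s$start_min),
         mean_rate_um2_min = sum(s$area_change_um2) / sum(s$end_min - s$start_min),
         n = nrow(s))
  })
  attr(seg, "summary") <- smry
  attr(seg, "epsilon") <- epsilon
  seg
}

#' Kinetics of apical nuclear travel during extrusion
#'
#' The nucleus of an extruding enterocyte ejects rapidly into the lumen, then
#' recoils to rest on the apical epithelium. Given the per-frame signed
#' distance of the nuclear centroid from the basal plane (apical positive),
#' this measures onset, peak, duration and recoil of the apical travel.
#' Onset is the first frame at which the distance exceeds the pre-rise
#' baseline (median of an initial window) by an onset threshold of
#' `max(mad_mult * MAD, onset_min_um)` for at least `persist` consecutive
#' frames; duration runs from onset to the distance maximum.
#'
#' @param t_min Frame times in minutes.
#' @param dist_um Signed centroid-to-basal-plane distances (um), apical
#'   positive; same length as `t_min`.
#' @param baseline_frames Number of initial frames used for the baseline
#'   (default 5, capped at the series length).
#' @param mad_mult Multiplier on the baseline MAD (default 2).
#' @param onset_min_um Floor on the onset threshold in um (default 0.5), so a
#'   noiseless flat baseline does not trigger on numeric dust.
#' @param persist Consecutive frames required above threshold (default 2).
#' @param plateau_frames Frames at the series end whose median defines the
#'   final plateau for the recoil amplitude (default 3).
#' @return A list with `event` (logical), and when an event is found:
#'   `start_min`, `peak_min`, `duration_min`, `peak_um`, `recoil_um`,
#'   `baseline_um` and the `distance` data.frame.
#' @export
nuclear_travel <- function(t_min, dist_um, baseline_frames = 5L, mad_mult = 2,
                           onset_min_um = 0.5, persist = 2L,
                           plateau_frames = 3L) {
  t_min <- as.numeric(t_min); dist_um <- as.numeric(dist_um)
  n <- length(t_min)
  if (length(dist_um) != n) stop("'t_min' and 'dist_um' lengths differ")
  if (n < 3L) stop("need at least 3 frames")
  if (any(diff(t_min) <= 0)) stop("'t_min' must be strictly increasing")
  k <- min(as.integer(baseline_frames), n)
  baseline <- median(dist_um[seq_len(k)])
  thr <- baseline + max(mad_mult * mad(dist_um[seq_len(k)]), onset_min_um)

  above <- dist_um > thr
  start_idx <- NA_integer_
  persist <- max(1L, as.integer(persist))
  for (i in seq_len(n - persist + 1L)) {
    if (all(above[i:(i + persist - 1L)])) { start_idx <- i; break }
  }
  series <- data.frame(t_min = t_min, dist_um = dist_um)
  if (is.na(start_idx)) {
    return(list(event = FALSE, reason = "no sustained rise above baseline",
                baseline_um = baseline, distance = series))
  }
  peak_idx <- which.max(dist_um)
  if (peak_idx < start_idx) {
    return(list(event = FALSE, reason = "distance maximum precedes onset",
                baseline_um = baseline, distance = series))
  }
  plateau <- median(tail(dist_um, min(plateau_frames, n)))
  list(event = TRUE,
       start_min = t_min[start_idx],
       peak_min = t_min[peak_idx],
       duration_min = t_min[peak_idx] - t_min[start_idx],
       peak_um = dist_um[peak_idx],
       recoil_um = dist_um[peak_idx] - plateau,
       baseline_um = baseline,
       distance = series)
}
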