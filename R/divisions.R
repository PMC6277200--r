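#' Duration of one mitosis
#'
#' Mitosis runs from the initiation of nuclear condensation in the mother cell
#' to the decondensation of the two sets of daughter chromosomes.
#'
#' @param record A mitosis record: any list with numeric `t_condense_min` and
#'   `t_decondense_min` fields (see [generate_mitosis_event()]), or the two
#'   times given directly.
#' @param t_decondense_min Optional; if supplied, `record` is taken as
#'   `t_condense_min`.
#' @return Duration in minutes.
#' @examples
#' mitosis_duration(0, 45)
#' @export
mitosis_duration <- function(record, t_decondense_min = NULL) {
  if (!is.null(t_decondense_min)) {
    t0 <- record; t1 <- t_decondense_min
  } else {
    t0 <- record$t_condense_min; t1 <- record$t_decondense_min
  }
  if (is.null(t0) || is.null(t1) || is.na(t0) || is.na(t1))
    stop("both condensation and decondensation times must be annotated")
  if (t1 <= t0) stop("decondensation must come after condensation")
  t1 - t0
}

#' Mitotic index T_M / T_SC
#'
#' The mitotic index of the imaged epithelium is the summed duration of all
#' observed mitoses (T_M) divided by the summed stem-cell 'screen time'
#' (T_SC). Screen time per movie is the product of the number of stem cells
#' at t = 0 and the movie duration; stem cells appearing or disappearing
#' mid-movie are ignored. When a movie lacks cell-type markers its stem-cell
#' count is estimated as `stem_estimate_fraction` of its total nuclei.
#'
#' @param durations_min Numeric vector of individual mitosis durations (min).
#'   May be empty (index 0).
#' @param movies A data.frame with one row per movie: `duration_min` and
#'   either `stem_count` (observed) or `total_cells` (for the estimate).
#'   Rows with both use `stem_count`.
#' @param stem_estimate_fraction Fraction of total nuclei assumed to be stem
#'   cells when only `total_cells` is given (default 0.20).
#' @return Dimensionless fraction T_M / T_SC.
#' @examples
#' mitotic_index(30, data.frame(stem_count = 10, duration_min = 600)) # 0.005
#' @export
mitotic_index <- function(durations_min, movies, stem_estimate_fraction = 0.20) {
  durations_min <- as.numeric(durations_min)
  if (any(durations_min <= 0)) stop("mitosis durations must be positive")
  if (!is.data.frame(movies) || !"duration_min" %in% names(movies))
    stop("'movies' must be a data.frame with a 'duration_min' column")
  stem <- if ("stem_count" %in% names(movies)) movies$stem_count else
    rep(NA_real_, nrow(movies))
  need <- is.na(stem)
  if (any(need)) {
    if (!"total_cells" %in% names(movies))
      stop("movies without 'stem_count' need a 'total_cells' column")
    stem[need] <- stem_estimate_fraction * movies$total_cells[need]
  }
  if (any(stem < 0) || any(movies$duration_min <= 0))
    stop("stem counts must be >= 0 and movie durations > 0")
  t_sc <- sum(stem * movies$duration_min)
  if (t_sc == 0) stop("total stem-cell screen time T_SC is zero")
  sum(durations_min) / t_sc
}

#' Horizontal-vertical spindle orientation
#'
#' Angle between the spindle-pole axis and the basal epithelial plane, folded
#' into `[0, 90]` degrees: 0 is a horizontal division (spindle in the plane),
#' 90 a vertical one (spindle along the plane normal). Computed from the dot
#' product of the unit spindle vector with the plane's unit normal
#' (`angle_hv = 90 - angle(spindle, normal)`).
#'
#' @param pole1,pole2 Spindle pole positions (um).
#' @param plane A [fit_basal_plane()] object.
#' @return Angle in degrees in `[0, 90]`.
#' @examples
#' pl <- fit_basal_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' angle_hv(c(0, 0, 0), c(1, 0, 1), pl) # 45
#' @export
angle_hv <- function(pole1, pole2, plane) {
  if (!inherits(plane, "basal_plane")) stop("'plane' must be a basal_plane object")
  v <- as_point3(pole2, "pole2") - as_point3(pole1, "pole1")
  if (vec_norm(v) < .Machine$double.eps) stop("spindle poles coincide")
  s <- abs(sum(unit_vec(v) * plane$normal))
  rad2deg(asin(min(1, s)))
}

#' Longitudinal-circumferential division orientation
#'
#' Angle between the daughter-daughter axis and the longitudinal axis of the
#' midgut tube, folded into `[0, 90]` degrees: 0 is a longitudinal division,
#' 90 a circumferential one. If `normal` is supplied the daughter vector is
#' first projected onto the epithelial plane, so the measurement is purely
#' in-plane (equivalent to measuring on a projected image).
#'
#' @param daughter1,daughter2 Daughter positions at cytokinesis (um).
#' @param axis Unit vector of the local longitudinal tube axis.
#' @param normal Optional plane normal for in-plane projection.
#' @return Angle in degrees in `[0, 90]`.
#' @export
angle_lc <- function(daughter1, daughter2, axis, normal = NULL) {
  d <- as_point3(daughter2, "daughter2") - as_point3(daughter1, "daughter1")
  if (vec_norm(d) < .Machine$double.eps) stop("daughter positions coincide")
  a <- unit_vec(as_point3(axis, "axis"))
  if (!is.null(normal)) {
    nrm <- unit_vec(as_point3(normal, "normal"))
    d <- d - sum(d * nrm) * nrm
    a <- a - sum(a * nrm) * nrm
    if (vec_norm(d) < 1e-12 || vec_norm(a) < 1e-12)
      stop("in-plane projection collapsed the daughter or axis vector")
  }
  co <- abs(sum(unit_vec(d) * unit_vec(a)))
  rad2deg(acos(min(1, co)))
}

#' Division orientation relative to neighboring enteroblasts
#'
#' When a dividing cell contacts one or two enteroblasts, the division can be
#' measured against the enteroblast axis. The reference enteroblast is the
#' sole contacting one, or, with two, the one whose nucleus was closer to the
#' mother stem-cell nucleus before division. D1 is the daughter closer to the
#' reference enteroblast; the angle between the EB-to-D1 vector and the
#' D1-to-D2 vector, folded into `[0, 90]` degrees, is 0 when the division is
#' parallel to the enteroblast axis.
#'
#' @param daughters 2 x 3 matrix of daughter positions at cytokinesis (um).
#' @param enteroblasts 1 x 3 or 2 x 3 matrix of contacting enteroblast
#'   nucleus positions (um).
#' @param mother Mother-cell nucleus position before division; required when
#'   two enteroblasts are given.
#' @param tie_tol If the reference enteroblast is equidistant (within
#'   `tie_tol` um) from both daughters, the lower-index daughter is D1 and the
#'   result is flagged.
#' @return Angle in degrees in `[0, 90]`, with attribute `"tie"` (logical)
#'   and `"d1"` (index of the daughter used as D1).
#' @export
angle_eb <- function(daughters, enteroblasts, mother = NULL, tie_tol = 1e-9) {
  daughters <- as.matrix(daughters)
  enteroblasts <- as.matrix(enteroblasts)
  if (!all(dim(daughters) == c(2L, 3L))) stop("'daughters' must be a 2 x 3 matrix")
  if (ncol(enteroblasts) != 3L || !nrow(enteroblasts) %in% 1:2)
    stop("'enteroblasts' must be a 1 x 3 or 2 x 3 matrix")
  if (nrow(enteroblasts) == 2L) {
    if (is.null(mother))
      stop("the mother position is required to pick between two enteroblasts")
    mother <- as_point3(mother, "mother")
    dm <- apply(enteroblasts, 1L, function(e) vec_norm(e - mother))
    eb <- enteroblasts[which.min(dm), ]
  } else {
    eb <- enteroblasts[1L, ]
  }
  d_eb <- apply(daughters, 1L, function(d) vec_norm(d - eb))
  tie <- abs(d_eb[1L] - d_eb[2L]) <= tie_tol
  i1 <- if (tie) 1L else which.min(d_eb)
  d1 <- daughters[i1, ]; d2 <- daughters[if (i1 == 1L) 2L else 1L, ]
  u <- d1 - eb
  v <- d2 - d1
  if (vec_norm(v) < .Machine$double.eps) stop("daughter positions coincide")
  if (vec_norm(u) < .Machine$double.eps)
    stop("reference enteroblast coincides with daughter D1")
  co <- abs(sum(unit_vec(u) * unit_vec(v)))
  structure(rad2deg(acos(min(1, co))), tie = tie, d1 = i1)
}

#' Count spindle re-orientation events
#'
#' Mitotic stem cells frequently re-orient; a re-orientation event is a
#' frame-to-frame change in horizontal-vertical orientation of at least
#' `threshold` degrees.
#'
#' @param angles_deg Per-frame horizontal-vertical angles (degrees).
#' @param threshold Minimum absolute change per frame step (degrees).
#' @return Integer count of re-orientation events.
#' @examples
#' reorientation_events(c(24, 60, 62, 2), 30) # 2
#' @export
reorientation_events <- function(angles_deg, threshold) {
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) < 2L) stop("need at least 2 frames")
  stopifnot_scalar_num(threshold, "threshold")
  sum(abs(diff(angles_deg)) >= threshold)
}
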