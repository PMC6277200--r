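#' Normalized GFP:RFP Notch-activation metric
#'
#' Notch pathway activation is read out as the ratio of a Notch
#' transcriptional reporter (GFP) to a ubiquitous nuclear reference (RFP).
#' To compare cells across movies acquired with different gains, each
#' channel's raw intensities are first normalized to a 0-to-1 scale by
#' dividing by the maximum intensity of that channel *in that movie* (over
#' all cells and frames); the per-cell, per-frame ratio of normalized GFP to
#' normalized RFP is then invariant to per-movie multiplicative gain.
#'
#' @param tracks A track table (see [generate_tracks()] / [read_tracks()])
#'   with columns `movie_id`, `cell_id`, `frame`, `t_min`, `gfp_raw`,
#'   `rfp_raw`, and optionally `label`. If `label` is present only esg+
#'   progenitors (`stem`, `enteroblast`) get ratios; other rows are dropped.
#' @param norm_quantile Normalize by this upper quantile of each channel
#'   instead of the literal maximum (e.g. `0.999` for robustness). Default
#'   `NULL` uses the maximum, matching the original protocol.
#' @return A data.frame (class `ratio_series`) with columns `movie_id`,
#'   `cell_id`, `frame`, `t_min`, `ratio`, `valid`. Frames with zero
#'   normalized RFP are flagged `valid = FALSE` with `ratio = NA` rather than
#'   propagating infinities.
#' @export
normalize_ratios <- function(tracks, norm_quantile = NULL) {
  req <- c("movie_id", "cell_id", "frame", "t_min", "gfp_raw", "rfp_raw")
  miss <- setdiff(req, names(tracks))
  if (length(miss)) stop("track table lacks column(s): ", paste(miss, collapse = ", "))

  norm_fun <- if (is.null(norm_quantile)) max else
    function(x) quantile(x, norm_quantile, names = FALSE)

  out <- lapply(split(tracks, tracks$movie_id), function(m) {
    # channel maxima are taken over *all* cells and frames of the movie;
    # ratios are then reported for esg+ progenitors only
    gmax <- norm_fun(m$gfp_raw)
    rmax <- norm_fun(m$rfp_raw)
    if (gmax <= 0 || rmax <= 0)
      stop("movie '", m$movie_id[1L], "' has non-positive channel maxima")
    if ("label" %in% names(m))
      m <- m[m$label %in% c("stem", "enteroblast"), , drop = FALSE]
    if (!nrow(m)) stop("no esg+ progenitor rows to normalize")
    gn <- m$gfp_raw / gmax
    rn <- m$rfp_raw / rmax
    valid <- rn > 0
    data.frame(movie_id = m$movie_id, cell_id = m$cell_id, frame = m$frame,
               t_min = m$t_min,
               ratio = ifelse(valid, gn / rn, NA_real_),
               valid = valid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$movie_id, out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ratio_series", "data.frame")
  out
}

#' Estimate the enteroblast fate threshold from pooled ratios
#'
#' The pooled distribution of normalized GFP:RFP values over all esg+
#' progenitors is bimodal: a sharp low mode (stem cells) and a broad high
#' mode (enteroblasts), separated by a local density minimum that serves as
#' the fate threshold. A Gaussian kernel density (Silverman bandwidth) is
#' evaluated on values clipped to `[0, 2]`; the two highest local maxima are
#' the modes and the density minimum strictly between them is the threshold,
#' reported at a grid resolution of 0.001.
#'
#' @param ratios Numeric vector of pooled ratio values (>= 100 values).
#' @param bw Kernel bandwidth passed to [stats::density()] (default
#'   `"nrd0"`, Silverman's rule).
#' @param grid_step Reporting resolution for the threshold (default 0.001).
#' @return List with `threshold`, `modes` (low, high), and the density
#'   object.
#' @export
estimate_threshold <- function(ratios, bw = "nrd0", grid_step = 0.001) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 100L) stop("need at least 100 ratio values")
  ratios <- pmin(pmax(ratios, 0), 2)
  d <- density(ratios, bw = bw, from = 0, to = max(ratios), n = 2048)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_max)
  # the second mode must be separated from the first by a genuine valley:
  # the density minimum between the two peaks has to drop below 80% of the
  # smaller peak, otherwise sampling wiggles on a unimodal density would
  # masquerade as modes
  top2 <- NULL
  if (length(peaks) >= 2L) {
    p1 <- peaks[which.max(y[peaks])]
    # a genuine second mode is not a tail wiggle: at least 5% of the main
    # peak's height (the broad enteroblast mode sits near 15% of the sharp
    # stem mode in pooled midgut data)
    others <- setdiff(peaks[y[peaks] >= 0.05 * y[p1]], p1)
    for (p2 in others[order(y[others], decreasing = TRUE)]) {
      lo <- min(p1, p2); hi <- max(p1, p2)
      if (hi - lo < 2L) next
      valley <- min(y[(lo + 1L):(hi - 1L)])
      if (valley < 0.8 * min(y[p1], y[p2])) {
        top2 <- c(lo, hi)
        break
      }
    }
  }
  if (is.null(top2))
    stop("pooled ratio density is unimodal; no fate threshold exists")
  lo <- top2[1L]; hi <- top2[2L]
  # refine the minimum on a fixed-step grid between the two modes
  grid <- seq(d$x[lo], d$x[hi], by = grid_step)
  gy <- approx(d$x, y, xout = grid)$y
  thr <- grid[which.min(gy)]
  list(threshold = thr,
       modes = c(d$x[lo], d$x[hi]),
       density = d)
}

#' Benchmark stem-cell validation of the fate threshold
#'
#' Mitosis is near-exclusive to stem cells, so cells observed to divide are
#' known stem cells independent of their reporter ratio. Their GFP:RFP values
#' at all frames before nuclear condensation form a 'benchmark' collection;
#' the fraction below the fate threshold validates the threshold.
#'
#' @param ratio_series A [normalize_ratios()] table.
#' @param mitoses A data.frame with `cell_id` and `t_condense_min` (and
#'   optionally `movie_id`) identifying pre-mitotic cells.
#' @param threshold Fate threshold (e.g. from [estimate_threshold()]).
#' @return List with `fraction_below`, `n_values`, `n_cells`.
#' @export
benchmark_stem_fraction <- function(ratio_series, mitoses, threshold) {
  stopifnot_scalar_num(threshold, "threshold", positive = TRUE)
  vals <- numeric(0); cells <- character(0)
  for (i in seq_len(nrow(mitoses))) {
    cid <- mitoses$cell_id[i]
    sel <- ratio_series$cell_id == cid &
      ratio_series$t_min < mitoses$t_condense_min[i] &
      ratio_series$valid
    if ("movie_id" %in% names(mitoses))
      sel <- sel & ratio_series$movie_id == mitoses$movie_id[i]
    v <- ratio_series$ratio[sel]
    if (length(v)) {
      vals <- c(vals, v)
      cells <- c(cells, as.character(cid))
    }
  }
  if (!length(vals)) stop("no pre-mitotic frames found for any benchmark cell")
  list(fraction_below = mean(vals < threshold),
       n_values = length(vals),
       n_cells = length(unique(cells)))
}

# transition detection for one cell's series; returns NULL or a one-row df
.transition_one <- function(t_min, ratio, valid, threshold, persistence_frames,
                            baseline_window) {
  ok <- valid & is.finite(ratio)
  t <- t_min[ok]; r <- ratio[ok]
  n <- length(r)
  if (n < persistence_frames + 1L) return(NULL)
  above <- r >= threshold - 1e-9  # reaching the threshold counts as crossing
  if (all(above)) {
    return(data.frame(status = "already_enteroblast", baseline_ratio = NA,
                      baseline_min = NA, crossing_min = NA,
                      duration_hr = NA, final_ratio = r[n]))
  }
  # persistent upward crossing: first frame at/above threshold that stays
  # at/above for persistence_frames consecutive frames
  cross <- NA_integer_
  for (i in seq_len(n - persistence_frames + 1L)) {
    if (all(above[i:(i + persistence_frames - 1L)]) &&
        (i == 1L || !above[i - 1L])) {
      if (i > 1L) { cross <- i; break }
    }
  }
  # persistent reversion: starts above, falls below and stays below
  reverted <- FALSE; revert_min <- NA_real_
  if (above[1L]) {
    below <- !above
    for (i in seq_len(n - persistence_frames + 1L)) {
      if (all(below[i:(i + persistence_frames - 1L)])) {
        reverted <- TRUE; revert_min <- t[i]; break
      }
    }
  }
  if (is.na(cross)) {
    if (reverted)
      return(data.frame(status = "reversion_candidate", baseline_ratio = NA,
                        baseline_min = revert_min, crossing_min = NA,
                        duration_hr = NA, final_ratio = r[n]))
    return(NULL)
  }
  # baseline time: end of the pre-rise flat period. First find the last
  # pre-crossing frame near the low pre-crossing level, then walk back down
  # the rise while the series keeps decreasing; on a flat baseline this
  # stops exactly at the last flat frame (the foot of the ramp).
  pre <- r[seq_len(cross - 1L)]
  low <- quantile(pre, 0.1, names = FALSE)
  tol <- 0.25 * max(threshold - low, 0)
  cand <- which(pre <= low + tol)
  j <- if (length(cand)) max(cand) else 1L
  while (j > 1L && r[j - 1L] < r[j]) j <- j - 1L
  base_idx <- seq(max(1L, j - baseline_window + 1L), j)
  baseline <- median(r[base_idx])
  if (baseline >= threshold) return(NULL)
  data.frame(status = "transition",
             baseline_ratio = baseline,
             baseline_min = t[j],
             crossing_min = t[cross],
             duration_hr = (t[cross] - t[j]) / 60,
             final_ratio = r[n])
}

#' Call enteroblast transitions from ratio time series
#'
#' A cell is scored as undergoing an enteroblast transition if its normalized
#' GFP:RFP persistently increases from below to above the fate threshold:
#' the crossing frame is the first frame at or above the threshold that stays
#' there for `persistence_frames` consecutive valid frames. The baseline is
#' the median of up to `baseline_window` frames ending at the last pre-rise
#' local minimum, and the transition duration runs from that baseline time to
#' the crossing. Cells entirely above the threshold are flagged
#' `already_enteroblast`; cells that start above and persistently fall below
#' are reported as `reversion_candidate`.
#'
#' @param ratio_series A [normalize_ratios()] table (or any data.frame with
#'   `cell_id`, `t_min`, `ratio`, `valid`).
#' @param threshold Fate threshold (default 0.17, the fallback when no
#'   threshold was estimated for the imaging system at hand).
#' @param persistence_frames Consecutive frames required above threshold
#'   (default 3).
#' @param baseline_window Frames entering the baseline median (default 6).
#' @return A data.frame with one row per scored cell: `cell_id`, `status`,
#'   `baseline_ratio`, `baseline_min`, `crossing_min`, `duration_hr`,
#'   `final_ratio`. Cells with no event are omitted.
#' @export
detect_transitions <- function(ratio_series, threshold = 0.17,
                               persistence_frames = 3L, baseline_window = 6L) {
  stopifnot_scalar_num(threshold, "threshold", positive = TRUE)
  persistence_frames <- max(1L, as.integer(persistence_frames))
  baseline_window <- max(1L, as.integer(baseline_window))
  res <- lapply(split(ratio_series, ratio_series$cell_id), function(s) {
    s <- s[order(s$t_min), , drop = FALSE]
    row <- .transition_one(s$t_min, s$ratio, s$valid, threshold,
                           persistence_frames, baseline_window)
    if (is.null(row)) return(NULL)
    cbind(data.frame(cell_id = s$cell_id[1L], stringsAsFactors = FALSE), row)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(cell_id = character(0), status = character(0),
                      baseline_ratio = numeric(0), baseline_min = numeric(0),
                      crossing_min = numeric(0), duration_hr = numeric(0),
                      final_ratio = numeric(0))
  rownames(res) <- NULL
  res
}

#' Euclidean inter-nuclear distance
#'
#' @param c1,c2 Nuclear centroids (um), length-3 vectors or n x 3 matrices.
#' @return Distance(s) in um.
#' @examples
#' internuclear_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
internuclear_distance <- function(c1, c2) {
  if (is.matrix(c1) || is.matrix(c2)) {
    c1 <- as.matrix(c1); c2 <- as.matrix(c2)
    if (!all(dim(c1) == dim(c2))) stop("centroid matrices differ in shape")
    if (any(!is.finite(c1)) || any(!is.finite(c2))) stop("coordinates must be finite")
    sqrt(rowSums((c2 - c1)^2))
  } else {
    vec_norm(as_point3(c2, "c2") - as_point3(c1, "c1"))
  }
}

#' Contact-state thresholds for inter-nuclear distance
#'
#' Calibration against membrane-marker movies showed that progenitor pairs
#' with inter-nuclear distance < 6.0 um are nearly always in contact and
#' pairs > 15.5 um nearly always separated; distances between the two bounds
#' are uninformative.
#'
#' @param contact_max Upper bound for inferred contact (um, default 6.0).
#' @param separation_min Lower bound for inferred separation (um, default
#'   15.5).
#' @return A `contact_thresholds` list.
#' @export
contact_thresholds <- function(contact_max = 6.0, separation_min = 15.5) {
  stopifnot_scalar_num(contact_max, "contact_max", positive = TRUE)
  stopifnot_scalar_num(separation_min, "separation_min", positive = TRUE)
  if (contact_max >= separation_min)
    stop("'contact_max' must be smaller than 'separation_min'")
  structure(list(contact_max = contact_max, separation_min = separation_min),
            class = "contact_thresholds")
}

#' Classify a nucleus pair's contact state from inter-nuclear distance
#'
#' Distances below `contact_max` are `contact`, above `separation_min`
#' `separated`, and the closed interval between the bounds (both boundary
#' values included) is `indeterminate`. The three states partition
#' `[0, Inf)`.
#'
#' @param distance_um Distance(s) in um, >= 0.
#' @param thresholds A [contact_thresholds()] object.
#' @return Character vector in `{"contact", "indeterminate", "separated"}`.
#' @examples
#' classify_contact(c(5.9, 6.0, 15.5, 20))
#' @export
classify_contact <- function(distance_um, thresholds = contact_thresholds()) {
  if (!inherits(thresholds, "contact_thresholds"))
    stop("'thresholds' must be a contact_thresholds object")
  distance_um <- as.numeric(distance_um)
  if (any(!is.finite(distance_um)) || any(distance_um < 0))
    stop("distances must be finite and >= 0")
  ifelse(distance_um < thresholds$contact_max, "contact",
         ifelse(distance_um > thresholds$separation_min, "separated",
                "indeterminate"))
}

#' Contact timeline of a sibling pair from birth
#'
#' Following a stem-cell division the two sibling nuclei are tracked and
#' their per-frame inter-nuclear distance classified into contact /
#' indeterminate / separated states. Summaries describe the pair's contact
#' dynamics: the longest maximal run of separated states (a pair 'separated
#' for at least one hour' has such a run spanning >= 60 min), the number of
#' direct separated-contact alternations (transitions between contact and
#' separated in the state sequence with indeterminate frames ignored), and
#' whether the pair appears permanently separated (final maximal run is
#' separated and reaches the end of co-observation).
#'
#' @param track1,track2 Data.frames for the two siblings with columns
#'   `frame`, `t_min`, `x_um`, `y_um`, `z_um`; only common frames are used
#'   and the tracks must share their birth frame.
#' @param thresholds A [contact_thresholds()] object.
#' @return List with `states` (data.frame: `frame`, `t_min`, `distance_um`,
#'   `state`) and `summary` (list: `longest_separation_min`,
#'   `n_alternations`, `permanent_separation`, `frac_contact`,
#'   `frac_indeterminate`, `frac_separated`).
#' @export
sibling_contact_timeline <- function(track1, track2,
                                     thresholds = contact_thresholds()) {
  common <- intersect(track1$frame, track2$frame)
  if (!length(common)) stop("sibling tracks share no frames")
  t1 <- track1[match(common, track1$frame), , drop = FALSE]
  t2 <- track2[match(common, track2$frame), , drop = FALSE]
  ord <- order(t1$frame)
  t1 <- t1[ord, ]; t2 <- t2[ord, ]
  if (min(track1$frame) != min(track2$frame))
    stop("sibling tracks must share their birth frame")
  d <- internuclear_distance(as.matrix(t1[, c("x_um", "y_um", "z_um")]),
                             as.matrix(t2[, c("x_um", "y_um", "z_um")]))
  state <- classify_contact(d, thresholds)
  tt <- t1$t_min

  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  sep_runs <- which(runs$values == "separated")
  longest_sep <- if (length(sep_runs))
    max(tt[ends[sep_runs]] - tt[starts[sep_runs]]) else 0

  cs <- state[state != "indeterminate"]
  cs <- rle(cs)$values
  n_alt <- if (length(cs) > 1L) sum(cs[-1L] != cs[-length(cs)]) else 0L

  permanent <- length(runs$values) > 0L &&
    runs$values[length(runs$values)] == "separated"

  list(states = data.frame(frame = t1$frame, t_min = tt, distance_um = d,
                           state = state, stringsAsFactors = FALSE),
       summary = list(
         longest_separation_min = longest_sep,
         n_alternations = n_alt,
         permanent_separation = permanent,
         frac_contact = mean(state == "contact"),
         frac_indeterminate = mean(state == "indeterminate"),
         frac_separated = mean(state == "separated")))
}

#' Flag frames with GFP bleed-over from a bright neighbor
#'
#' When a low-Notch cell collides with a bright, Notch-activated neighbor,
#' GFP signal from the neighbor bleeds into the cell's nuclear surface and
#' its GFP:RFP spikes artifactually. Frames where a cell lies within
#' `proximity_um` of a neighbor whose ratio exceeds `ratio_threshold` are
#' flagged invalid; they are excluded from transition calling but retained in
#' the output.
#'
#' @param tracks Track table with `movie_id`, `cell_id`, `frame`, `x_um`,
#'   `y_um`, `z_um`.
#' @param ratio_series A [normalize_ratios()] table for the same movie(s).
#' @param ratio_threshold Neighbor ratio above which bleed-over is assumed
#'   (default 0.5, a clearly mature enteroblast).
#' @param proximity_um Distance below which bleed-over can occur (default
#'   6.0, the inferred-contact bound).
#' @return The ratio series with `valid` set to FALSE on flagged frames and a
#'   logical `bleedover` column added.
#' @export
flag_bleedover <- function(tracks, ratio_series, ratio_threshold = 0.5,
                           proximity_um = 6.0) {
  ratio_series$bleedover <- FALSE
  key_rs <- paste(ratio_series$movie_id, ratio_series$cell_id,
                  ratio_series$frame)
  key_tr <- paste(tracks$movie_id, tracks$cell_id, tracks$frame)
  for (mf in split(seq_len(nrow(tracks)),
                   paste(tracks$movie_id, tracks$frame))) {
    sub <- tracks[mf, , drop = FALSE]
    if (nrow(sub) < 2L) next
    rs_idx <- match(paste(sub$movie_id, sub$cell_id, sub$frame), key_rs)
    ratio <- ratio_series$ratio[rs_idx]
    bright <- which(!is.na(ratio) & ratio > ratio_threshold)
    if (!length(bright)) next
    pos <- as.matrix(sub[, c("x_um", "y_um", "z_um")])
    for (i in seq_len(nrow(sub))) {
      if (is.na(rs_idx[i])) next
      nb <- setdiff(bright, i)
      if (!length(nb)) next
      dmin <- min(sqrt(rowSums((pos[nb, , drop = FALSE] -
                                  matrix(pos[i, ], length(nb), 3,
                                         byrow = TRUE))^2)))
      if (dmin < proximity_um) {
        ratio_series$bleedover[rs_idx[i]] <- TRUE
        ratio_series$valid[rs_idx[i]] <- FALSE
      }
    }
  }
  ratio_series
}
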