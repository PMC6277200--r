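#' Movie metadata
#'
#' @param movie_id Movie identifier string.
#' @param frame_interval_min Time between z-stacks in minutes (5-15 in
#'   typical acquisitions).
#' @param n_frames Number of time points (>= 2).
#' @param voxel_size_um Voxel size `(z, y, x)` in um.
#' @param channel_names Ordered channel names.
#' @return A `movie_meta` list; `duration_hr` is derived.
#' @export
movie_meta <- function(movie_id, frame_interval_min, n_frames,
                       voxel_size_um = c(2.98, 1, 1),
                       channel_names = c("cfp", "gfp", "rfp")) {
  stopifnot_scalar_num(frame_interval_min, "frame_interval_min", positive = TRUE)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0")
  structure(list(movie_id = as.character(movie_id),
                 frame_interval_min = frame_interval_min,
                 n_frames = n_frames,
                 voxel_size_um = as.numeric(voxel_size_um),
                 channel_names = channel_names,
                 duration_hr = n_frames * frame_interval_min / 60),
            class = "movie_meta")
}

.track_columns <- c("movie_id", "cell_id", "frame", "t_min", "x_um", "y_um",
                    "z_um", "volume_um3", "cfp_raw", "gfp_raw", "rfp_raw")

#' Read a track table CSV
#'
#' The track schema has one row per living cell per time point: `movie_id`,
#' `cell_id`, `frame` (0-based), `t_min`, `x_um`, `y_um`, `z_um`,
#' `volume_um3`, `cfp_raw`, `gfp_raw`, `rfp_raw` and an optional `label`.
#' Rows are grouped by cell and sorted by frame; frames missing between a
#' cell's first and last appearance are reported in the `"gaps"` attribute.
#'
#' @param path CSV file path.
#' @return List with `tracks` (data.frame, sorted, with attribute `"gaps"`)
#'   and `meta` (a [movie_meta()] inferred per movie, as a list keyed by
#'   movie id).
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.track_columns, names(df))
  if (length(miss))
    stop("track CSV lacks required column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$movie_id, df$cell_id, df$frame, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicated (movie_id, cell_id, frame) row(s): ",
         paste(unique(dup), collapse = ", "))
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)) ||
      any(!is.finite(df$z_um)))
    stop("track coordinates must be finite")
  if (any(df$volume_um3 <= 0)) stop("nuclear volumes must be > 0")
  df <- df[order(df$movie_id, df$cell_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL

  gaps <- do.call(rbind, lapply(split(df, paste(df$movie_id, df$cell_id)),
                                function(s) {
    fr <- s$frame
    expect <- seq(min(fr), max(fr))
    mis <- setdiff(expect, fr)
    if (!length(mis)) return(NULL)
    data.frame(movie_id = s$movie_id[1L], cell_id = s$cell_id[1L],
               missing_frame = mis, stringsAsFactors = FALSE)
  }))
  attr(df, "gaps") <- gaps

  meta <- lapply(split(df, df$movie_id), function(m) {
    frames <- sort(unique(m$frame))
    dt <- if (length(frames) > 1L)
      median(diff(sort(unique(m$t_min)))) else NA_real_
    movie_meta(m$movie_id[1L], frame_interval_min = dt,
               n_frames = max(frames) + 1L)
  })
  list(tracks = df, meta = meta)
}

#' Write a track table CSV
#'
#' @param tracks Track data.frame (schema of [read_tracks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  miss <- setdiff(.track_columns, names(tracks))
  if (length(miss))
    stop("track table lacks required column(s): ", paste(miss, collapse = ", "))
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Read / write extrusion-ring vertex tables
#'
#' Ring CSVs have one row per vertex per frame: `movie_id`, `event_id`,
#' `frame`, `t_min`, `vertex_index` (0-5 for the typical six-sided ring),
#' `x_um`, `y_um`, `z_um`. Plane CSVs carry the three basal reference points
#' per frame: `movie_id`, `event_id`, `frame`, `point_index` (1-3), `x_um`,
#' `y_um`, `z_um`.
#'
#' @param path CSV file path.
#' @param rings,planes Data.frames in the schemas above.
#' @return `read_rings`/`read_planes` return the validated data.frame.
#' @name ring_io
NULL

#' @rdname ring_io
#' @export
read_rings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("movie_id", "event_id", "frame", "t_min", "vertex_index",
           "x_um", "y_um", "z_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("ring CSV lacks column(s): ", paste(miss, collapse = ", "))
  df[order(df$movie_id, df$event_id, df$frame, df$vertex_index), , drop = FALSE]
}

#' @rdname ring_io
#' @export
write_rings <- function(rings, path) {
  write.csv(rings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ring_io
#' @export
read_planes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("movie_id", "event_id", "frame", "point_index", "x_um", "y_um", "z_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("plane CSV lacks column(s): ", paste(miss, collapse = ", "))
  df[order(df$movie_id, df$event_id, df$frame, df$point_index), , drop = FALSE]
}

#' @rdname ring_io
#' @export
write_planes <- function(planes, path) {
  write.csv(planes, path, row.names = FALSE)
  invisible(path)
}

#' Read / write ground-truth records as JSON
#'
#' @param truth Ground-truth list from [generate_tracks()].
#' @param path JSON file path.
#' @return `read_ground_truth` returns the parsed list.
#' @name truth_io
NULL

#' @rdname truth_io
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname truth_io
#' @export
read_ground_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

# ring table (long format) -> per-frame list of vertex matrices
.ring_frames <- function(rings) {
  lapply(split(rings, rings$frame), function(s) {
    s <- s[order(s$vertex_index), , drop = FALSE]
    list(frame = s$frame[1L], t_min = s$t_min[1L],
         vertices = as.matrix(s[, c("x_um", "y_um", "z_um")]))
  })
}

# plane table -> per-frame basal_plane list
.plane_frames <- function(planes, apical_hint = NULL) {
  lapply(split(planes, planes$frame), function(s) {
    s <- s[order(s$point_index), , drop = FALSE]
    p <- as.matrix(s[, c("x_um", "y_um", "z_um")])
    fit_basal_plane(p[1L, ], p[2L, ], p[3L, ], apical_hint = apical_hint)
  })
}
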