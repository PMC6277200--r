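#' Linking configuration
#'
#' @param max_displacement Maximum allowed centroid displacement per frame
#'   step (um).
#' @param allow_gap Number of missed frames a track may bridge (default 0:
#'   a detection missing for one frame terminates the track).
#' @return A `link_config` list.
#' @export
link_config <- function(max_displacement, allow_gap = 0L) {
  stopifnot_scalar_num(max_displacement, "max_displacement", positive = TRUE)
  allow_gap <- as.integer(allow_gap)
  if (allow_gap < 0L) stop("'allow_gap' must be >= 0")
  structure(list(max_displacement = max_displacement, allow_gap = allow_gap),
            class = "link_config")
}

# deterministic nearest neighbor: smallest distance, ties broken by lower index
.nn_index <- function(d) {
  apply(d, 1L, function(row) which(row == min(row))[1L])
}

#' Link per-frame detections into nucleus tracks
#'
#' A deterministic stand-in for commercial Brownian-motion trackers: per
#' consecutive frame pair, open track heads and new detections are matched by
#' greedy mutual nearest neighbors in 3D, linking only when the distance is
#' at most `max_displacement`. Ties are broken by (distance, lower index).
#' Unmatched detections start new tracks; unmatched heads survive
#' `allow_gap` further frames before closing.
#'
#' @param detections A data.frame with columns `frame`, `x_um`, `y_um`,
#'   `z_um` and any per-detection extras (volume, intensities), one row per
#'   detection.
#' @param config A [link_config()] object.
#' @return The detections data.frame with a `cell_id` column (`"trk0001"`,
#'   ...), ordered by cell and frame.
#' @export
link_tracks <- function(detections, config) {
  if (!inherits(config, "link_config")) stop("'config' must be a link_config object")
  req <- c("frame", "x_um", "y_um", "z_um")
  miss <- setdiff(req, names(detections))
  if (length(miss)) stop("detections lack column(s): ", paste(miss, collapse = ", "))
  detections$.row <- seq_len(nrow(detections))
  detections$cell_id <- NA_character_
  frames <- sort(unique(detections$frame))
  next_id <- 0L
  new_id <- function() {
    next_id <<- next_id + 1L
    sprintf("trk%04d", next_id)
  }
  # heads: data.frame of open tracks
  heads <- data.frame(cell_id = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), last_frame = numeric(0),
                      stringsAsFactors = FALSE)
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    pos <- as.matrix(det[, c("x_um", "y_um", "z_um")])
    live <- heads[f - heads$last_frame <= config$allow_gap + 1L, , drop = FALSE]
    assigned <- rep(NA_character_, nrow(det))
    if (nrow(live) && nrow(det)) {
      hp <- as.matrix(live[, c("x", "y", "z")])
      d2 <- outer(rowSums(hp^2), rep(1, nrow(pos))) +
        outer(rep(1, nrow(hp)), rowSums(pos^2)) - 2 * hp %*% t(pos)
      d <- sqrt(pmax(d2, 0))
      nn_det <- .nn_index(d)        # for each head, its nearest detection
      nn_head <- .nn_index(t(d))    # for each detection, its nearest head
      for (h in seq_len(nrow(live))) {
        j <- nn_det[h]
        if (nn_head[j] == h && d[h, j] <= config$max_displacement) {
          assigned[j] <- live$cell_id[h]
        }
      }
    }
    for (j in seq_len(nrow(det))) {
      if (is.na(assigned[j])) assigned[j] <- new_id()
    }
    detections$cell_id[det$.row] <- assigned
    # update heads
    for (j in seq_len(nrow(det))) {
      k <- match(assigned[j], heads$cell_id)
      if (is.na(k)) {
        heads <- rbind(heads, data.frame(cell_id = assigned[j], x = pos[j, 1],
                                         y = pos[j, 2], z = pos[j, 3],
                                         last_frame = f,
                                         stringsAsFactors = FALSE))
      } else {
        heads$x[k] <- pos[j, 1]; heads$y[k] <- pos[j, 2]
        heads$z[k] <- pos[j, 3]; heads$last_frame[k] <- f
      }
    }
    # drop heads that have aged out (keeps the search small)
    heads <- heads[f - heads$last_frame <= config$allow_gap, , drop = FALSE]
    heads_this <- detections$cell_id[det$.row]
    # re-add heads updated this frame (aged filter above removed none of them)
    missing <- setdiff(heads_this, heads$cell_id)
    if (length(missing)) {
      sel <- match(missing, assigned)
      heads <- rbind(heads,
                     data.frame(cell_id = missing, x = pos[sel, 1],
                                y = pos[sel, 2], z = pos[sel, 3],
                                last_frame = f, stringsAsFactors = FALSE))
    }
  }
  detections$.row <- NULL
  detections <- detections[order(detections$cell_id, detections$frame), ,
                           drop = FALSE]
  rownames(detections) <- NULL
  detections
}

#' Find progenitor pairs by mutual nearest neighbors
#'
#' Two esg+ cells (stem or enteroblast) are designated a pair if they are
#' mutually closer to each other than to any other esg+ cell at that frame.
#' Each cell appears in at most one pair.
#'
#' @param positions A data.frame with `cell_id`, `x_um`, `y_um`, `z_um` for
#'   the esg+ cells at one frame (pre-filter by label and frame).
#' @return A data.frame with columns `cell_id1`, `cell_id2`,
#'   `distance_um`; empty when fewer than 2 cells are supplied.
#' @export
find_progenitor_pairs <- function(positions) {
  empty <- data.frame(cell_id1 = character(0), cell_id2 = character(0),
                      distance_um = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(positions)
  if (is.null(n) || n < 2L) return(empty)
  pos <- as.matrix(positions[, c("x_um", "y_um", "z_um")])
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  nn <- .nn_index(d)
  out <- empty
  for (i in seq_len(n)) {
    j <- nn[i]
    if (j > i && nn[j] == i) {
      out <- rbind(out, data.frame(cell_id1 = as.character(positions$cell_id[i]),
                                   cell_id2 = as.character(positions$cell_id[j]),
                                   distance_um = d[i, j],
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
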