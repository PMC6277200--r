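#' Typing configuration for segmentation and classification
#'
#' @param ee_volume_max Nuclear-volume cutoff in um^3 separating
#'   enteroendocrine cells (<= cutoff) from enterocytes (> cutoff) among
#'   mature (esg-negative) cells. Default 113.
#' @param threshold_method `"automatic"` (Otsu per channel) or `"fixed"`.
#' @param fixed_thresholds Named numeric vector of per-channel intensity
#'   thresholds, required when `threshold_method = "fixed"`.
#' @param min_component_volume Components smaller than this (um^3) are
#'   discarded as debris. Default 20.
#' @param connectivity Voxel connectivity for component labeling, 6 or 26
#'   (default 26: nuclei are compact blobs and spurious merging is handled by
#'   the minimum component volume).
#' @return A `typing_config` list.
#' @export
typing_config <- function(ee_volume_max = 113, threshold_method = c("automatic", "fixed"),
                          fixed_thresholds = NULL, min_component_volume = 20,
                          connectivity = 26L) {
  threshold_method <- match.arg(threshold_method)
  stopifnot_scalar_num(ee_volume_max, "ee_volume_max", positive = TRUE)
  if (!is.numeric(min_component_volume) || min_component_volume < 0)
    stop("'min_component_volume' must be >= 0")
  if (!connectivity %in% c(6L, 26L)) stop("'connectivity' must be 6 or 26")
  if (threshold_method == "fixed" && is.null(fixed_thresholds))
    stop("fixed threshold_method needs 'fixed_thresholds'")
  structure(list(ee_volume_max = ee_volume_max,
                 threshold_method = threshold_method,
                 fixed_thresholds = fixed_thresholds,
                 min_component_volume = min_component_volume,
                 connectivity = as.integer(connectivity)),
            class = "typing_config")
}

#' Otsu's threshold
#'
#' Histogram-based automatic intensity threshold maximizing between-class
#' variance; used per channel (and, if desired, per frame) when no fixed
#' threshold is configured.
#'
#' @param x Numeric vector or array of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite intensities")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  breaks[which.max(sigma_b) + 1L]
}

#' Segment nuclei in a single-channel volume by intensity thresholding
#'
#' Reimplements the segmentation route of the imaging workflow: the
#' ubiquitous nuclear channel is thresholded (Otsu by default), connected
#' components are labeled in 3D, components below the minimum volume are
#' discarded, and each component's intensity-weighted centroid (um) and
#' volume (voxel count x voxel volume, um^3) are reported.
#'
#' @param volume 3D numeric array in `(z, y, x)` order.
#' @param voxel_size_um Length-3 voxel size `(z, y, x)` in um.
#' @param config A [typing_config()]; for fixed thresholding the threshold is
#'   taken from `fixed_thresholds[channel]`.
#' @param channel Channel name used to look up a fixed threshold (default
#'   `"rfp"`).
#' @param origin_um Physical coordinate of the corner of voxel `[1,1,1]`
#'   (length-3, `(z, y, x)`; default zeros), added to centroids.
#' @return List with `components` (data.frame: `label`, `n_voxels`,
#'   `volume_um3`, `x_um`, `y_um`, `z_um`, `mean_intensity`) and `labels`
#'   (integer array of the same shape as `volume`). An all-background volume
#'   yields zero components, not an error.
#' @export
segment_nuclei <- function(volume, voxel_size_um, config = typing_config(),
                           channel = "rfp", origin_um = c(0, 0, 0)) {
  if (!inherits(config, "typing_config")) stop("'config' must be a typing_config")
  if (length(dim(volume)) != 3L) stop("'volume' must be a 3D array (z, y, x)")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("'voxel_size_um' must be 3 positive numbers (z, y, x)")
  origin_um <- as.numeric(origin_um)
  thr <- if (config$threshold_method == "fixed") {
    th <- config$fixed_thresholds
    if (!channel %in% names(th)) stop("no fixed threshold for channel '", channel, "'")
    th[[channel]]
  } else {
    if (all(volume == 0)) Inf else otsu_threshold(volume)
  }
  mask <- volume > thr
  empty <- list(components = data.frame(label = integer(0), n_voxels = integer(0),
                                        volume_um3 = numeric(0), x_um = numeric(0),
                                        y_um = numeric(0), z_um = numeric(0),
                                        mean_intensity = numeric(0)),
                labels = array(0L, dim(volume)), threshold = thr,
                voxel_size_um = voxel_size_um, origin_um = origin_um)
  if (!any(mask)) return(empty)
  labels <- array(.cc_label_3d(as.logical(mask), as.integer(dim(volume)),
                               config$connectivity), dim(volume))
  vox_vol <- prod(voxel_size_um)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  inten <- volume[idx]
  coords <- arrayInd(idx, dim(volume))  # columns: z, y, x indices
  counts <- tabulate(lab)
  keep <- which(counts * vox_vol >= config$min_component_volume)
  if (!length(keep)) return(empty)
  comp <- lapply(keep, function(l) {
    sel <- lab == l
    w <- inten[sel]
    ctr_idx <- colSums(coords[sel, , drop = FALSE] * w) / sum(w)
    # voxel centers sit at (index - 0.5) * voxel size
    ctr_um <- (ctr_idx - 0.5) * voxel_size_um + origin_um
    data.frame(label = l, n_voxels = counts[l],
               volume_um3 = counts[l] * vox_vol,
               x_um = ctr_um[3L], y_um = ctr_um[2L], z_um = ctr_um[1L],
               mean_intensity = mean(w))
  })
  comp <- do.call(rbind, comp)
  # zero out discarded labels
  drop <- setdiff(unique(lab), keep)
  if (length(drop)) labels[labels %in% drop] <- 0L
  rownames(comp) <- NULL
  list(components = comp, labels = labels, threshold = thr,
       voxel_size_um = voxel_size_um, origin_um = origin_um)
}

#' Channel-mask arithmetic separating the three nuclear populations
#'
#' The fate-sensor genotype marks stem cells with CFP+RFP, enteroblasts with
#' CFP+GFP+RFP, and mature cells (enterocytes, enteroendocrine) with RFP
#' only. The population masks reproduce the image-calculator recipe:
#' stem = CFP AND NOT GFP; enteroblast = GFP; mature = RFP AND NOT CFP.
#' Wherever every CFP+ voxel is also RFP+ (true of the genotype), the three
#' masks are mutually exclusive.
#'
#' @param cfp_mask,gfp_mask,rfp_mask Logical arrays of equal shape.
#' @return List of logical arrays `stem_mask`, `eb_mask`, `mature_mask`.
#' @export
mask_populations <- function(cfp_mask, gfp_mask, rfp_mask) {
  if (!identical(dim(cfp_mask), dim(gfp_mask)) ||
      !identical(dim(cfp_mask), dim(rfp_mask)) ||
      length(cfp_mask) != length(gfp_mask) ||
      length(cfp_mask) != length(rfp_mask))
    stop("channel masks differ in shape")
  list(stem_mask = cfp_mask & !gfp_mask,
       eb_mask = gfp_mask,
       mature_mask = rfp_mask & !cfp_mask)
}

#' Classify a mature (esg-negative) nucleus by its volume
#'
#' Mature nuclei at or below `ee_volume_max` (113 um^3 by default) are
#' enteroendocrine; larger, polyploid nuclei are enterocytes. The boundary
#' value is assigned to the enteroendocrine side.
#'
#' @param volume_um3 Nuclear volume(s) in um^3, > 0.
#' @param config A [typing_config()].
#' @return Character vector of `"enteroendocrine"` / `"enterocyte"`.
#' @examples
#' classify_mature(c(50, 113, 113.1))
#' @export
classify_mature <- function(volume_um3, config = typing_config()) {
  volume_um3 <- as.numeric(volume_um3)
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0))
    stop("nuclear volumes must be positive")
  ifelse(volume_um3 <= config$ee_volume_max, "enteroendocrine", "enterocyte")
}

#' Per-cell mean raw intensities from labeled components
#'
#' @param seg A [segment_nuclei()] result (its `labels` array is used).
#' @param channels Named list of intensity arrays with the same shape as the
#'   segmented volume.
#' @param labels Optional integer vector restricting extraction to these
#'   component labels; an absent label is an error.
#' @return Data.frame with `label` and one mean-intensity column per channel.
#' @export
extract_intensities <- function(seg, channels, labels = NULL) {
  lab_arr <- seg$labels
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a named list of arrays")
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dim(lab_arr)))
      stop("channel '", nm, "' does not match the segmented volume's shape")
  }
  present <- sort(unique(as.integer(lab_arr[lab_arr > 0L])))
  if (is.null(labels)) labels <- present
  missing <- setdiff(labels, present)
  if (length(missing))
    stop("label(s) absent from segmentation: ", paste(missing, collapse = ", "))
  idx_all <- which(lab_arr > 0L)
  lab_vec <- lab_arr[idx_all]
  out <- data.frame(label = labels)
  for (nm in names(channels)) {
    v <- channels[[nm]][idx_all]
    means <- tapply(v, lab_vec, mean)
    out[[paste0(nm, "_mean")]] <- as.numeric(means[as.character(labels)])
  }
  out
}

#' Type segmented nuclei from population masks and the size filter
#'
#' Convenience glue for the end-to-end route: each segmented nucleus is
#' assigned to the population whose mask covers the majority of its voxels
#' (stem / enteroblast / mature), and mature nuclei are split into
#' enteroendocrine and enterocyte by the volume filter.
#'
#' @param seg A [segment_nuclei()] result (segmented on the all-nuclei
#'   channel).
#' @param masks A [mask_populations()] result.
#' @param config A [typing_config()].
#' @return The `seg$components` data.frame with an added `label_type` column
#'   (one of stem, enteroblast, enterocyte, enteroendocrine).
#' @export
type_cells <- function(seg, masks, config = typing_config()) {
  comp <- seg$components
  lab_arr <- seg$labels
  idx_all <- which(lab_arr > 0L)
  lab_vec <- lab_arr[idx_all]
  frac <- function(mask) {
    m <- mask[idx_all]
    as.numeric(tapply(m, lab_vec, mean)[as.character(comp$label)])
  }
  f_stem <- frac(masks$stem_mask)
  f_eb <- frac(masks$eb_mask)
  f_mat <- frac(masks$mature_mask)
  type <- character(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    scores <- c(stem = f_stem[i], enteroblast = f_eb[i], mature = f_mat[i])
    best <- names(scores)[which.max(scores)]
    type[i] <- if (best == "mature")
      classify_mature(comp$volume_um3[i], config) else best
  }
  comp$label_type <- type
  comp
}
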