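# Minimal multi-page TIFF I/O (little-endian, uncompressed, 32-bit float,
# one strip per page). No TIFF-capable R package is available in the target
# environment, so the subset of baseline TIFF needed for synthetic volumes is
# implemented here. Stack metadata (axis order, shape, voxel size, channel
# names, origin) is carried in the first page's ImageDescription as JSON and
# is readable by standard tools.

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L)

.write_ifd_entry <- function(con, tag, type, count, value_bytes) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  stopifnot(length(value_bytes) == 4L)
  writeBin(value_bytes, con)
}

.le2 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write an image stack as multi-page TIFF
#'
#' Pages are uncompressed 32-bit float, little-endian, one strip per page.
#' The first page's ImageDescription records a JSON blob with the axis
#' order, array shape, voxel size (um), channel names and physical origin,
#' from which [read_volume()] restores the canonical `(t, c, z, y, x)`
#' array.
#'
#' @param stack 5D numeric array; dimension order given by `axes`.
#' @param path Output file path.
#' @param voxel_size_um Length-3 voxel size `(z, y, x)` in um (required
#'   unless `meta = FALSE`).
#' @param axes Five-character permutation of `"tczyx"` describing the
#'   dimension order of `stack`; must end in `"yx"`. Default canonical.
#' @param channel_names Optional character vector, length = channel count.
#' @param origin_um Physical coordinate of the volume corner, `(z, y, x)` um.
#' @param meta Write the metadata description (default TRUE). `FALSE`
#'   produces a bare TIFF that cannot be re-read without overrides.
#' @return `path`, invisibly.
#' @export
write_volume <- function(stack, path, voxel_size_um = NULL, axes = "tczyx",
                         channel_names = NULL, origin_um = c(0, 0, 0),
                         meta = TRUE) {
  dims <- dim(stack)
  if (length(dims) != 5L) stop("'stack' must be a 5D array")
  ax <- strsplit(axes, "")[[1]]
  if (length(ax) != 5L || !setequal(ax, c("t", "c", "z", "y", "x")) ||
      !identical(ax[4:5], c("y", "x")))
    stop("'axes' must be a permutation of 'tczyx' ending in 'yx'")
  if (meta && (is.null(voxel_size_um) || length(voxel_size_um) != 3L))
    stop("'voxel_size_um' (z, y, x) is required")
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]; ny <- dims[4]; nx <- dims[5]
  n_pages <- d1 * d2 * d3
  page_bytes <- nx * ny * 4L

  desc <- if (meta) {
    nchan <- dims[match("c", ax)]
    jsonlite::toJSON(list(
      axes = axes, shape = as.integer(dims),
      voxel_size_um = as.numeric(voxel_size_um),
      channel_names = channel_names %||% paste0("ch", seq_len(nchan)),
      origin_um = as.numeric(origin_um)), auto_unbox = TRUE, digits = NA)
  } else NULL
  desc_raw <- if (!is.null(desc)) c(charToRaw(as.character(desc)), as.raw(0L)) else raw(0)
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  data_off <- 8L + (seq_len(n_pages) - 1L) * page_bytes
  desc_off <- 8L + n_pages * page_bytes
  ifd0_off <- desc_off + length(desc_raw)
  n_entries <- function(p) if (p == 1L && !is.null(desc)) 11L else 10L
  ifd_size <- function(p) 2L + 12L * n_entries(p) + 4L
  ifd_off <- integer(n_pages)
  off <- ifd0_off
  for (p in seq_len(n_pages)) {
    ifd_off[p] <- off
    off <- off + ifd_size(p)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd0_off), con, size = 4, endian = "little")

  # pixel data, page-major with the third stored axis fastest
  for (i1 in seq_len(d1)) for (i2 in seq_len(d2)) for (i3 in seq_len(d3)) {
    m <- stack[i1, i2, i3, , ]
    dim(m) <- c(ny, nx)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  }
  if (length(desc_raw)) writeBin(desc_raw, con)

  for (p in seq_len(n_pages)) {
    ne <- n_entries(p)
    writeBin(as.integer(ne), con, size = 2, endian = "little")
    short_val <- function(v) c(.le2(v), as.raw(c(0, 0)))
    .write_ifd_entry(con, 256L, .tiff_types[["LONG"]], 1L, .le4(nx))
    .write_ifd_entry(con, 257L, .tiff_types[["LONG"]], 1L, .le4(ny))
    .write_ifd_entry(con, 258L, .tiff_types[["SHORT"]], 1L, short_val(32L))
    .write_ifd_entry(con, 259L, .tiff_types[["SHORT"]], 1L, short_val(1L))
    .write_ifd_entry(con, 262L, .tiff_types[["SHORT"]], 1L, short_val(1L))
    if (p == 1L && !is.null(desc))
      .write_ifd_entry(con, 270L, .tiff_types[["ASCII"]], length(desc_raw),
                       .le4(desc_off))
    .write_ifd_entry(con, 273L, .tiff_types[["LONG"]], 1L, .le4(data_off[p]))
    .write_ifd_entry(con, 277L, .tiff_types[["SHORT"]], 1L, short_val(1L))
    .write_ifd_entry(con, 278L, .tiff_types[["LONG"]], 1L, .le4(ny))
    .write_ifd_entry(con, 279L, .tiff_types[["LONG"]], 1L, .le4(page_bytes))
    .write_ifd_entry(con, 339L, .tiff_types[["SHORT"]], 1L, short_val(3L))
    next_off <- if (p < n_pages) ifd_off[p + 1L] else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_tiff_pages <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = sz)
  if (length(raw_all) < 8L || rawToChar(raw_all[1:2]) != "II")
    stop("not a little-endian TIFF file")
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (u16(2L) != 42L) stop("not a TIFF file (bad magic)")
  ifd_off <- u32(4L)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    ne <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(ne)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      tag <- u16(base); type <- u16(base + 2L); count <- u32(base + 4L)
      val <- if (type == 3L && count == 1L) u16(base + 8L) else u32(base + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
    }
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) stop("TIFF page lacks required tag ", tag)
        return(default)
      }
      t$value
    }
    if (need(259, 1) != 1) stop("compressed TIFF not supported")
    if (need(258, 32) != 32 || need(339, 1) != 3)
      stop("only 32-bit float TIFF pages are supported")
    nx <- need(256); ny <- need(257)
    so <- tags[["273"]]; sc <- tags[["279"]]
    if (is.null(so) || is.null(sc)) stop("TIFF page lacks strip tags")
    if (so$count != 1L) stop("multi-strip TIFF pages not supported")
    nbytes <- sc$value
    vals <- readBin(raw_all[so$value + seq_len(nbytes)], "numeric",
                    n = nbytes / 4L, size = 4, endian = "little")
    m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
    pages[[length(pages) + 1L]] <- m
    dtag <- tags[["270"]]
    if (!is.null(dtag) && is.null(description)) {
      draw <- raw_all[dtag$value + seq_len(dtag$count)]
      draw <- draw[draw != as.raw(0L)]
      description <- rawToChar(draw)
    }
    ifd_off <- u32(ifd_off + 2L + ne * 12L)
  }
  list(pages = pages, description = description)
}

#' Read an image stack from multi-page TIFF
#'
#' Restores the canonical `(t, c, z, y, x)` array. Axis order, shape and
#' voxel size are taken from the JSON ImageDescription written by
#' [write_volume()]; files without that metadata need the `axes`, `shape`
#' and `voxel_size_um` overrides, otherwise an error is raised.
#'
#' @param path TIFF file path.
#' @param axes Override for the stored dimension order (permutation of
#'   `"tczyx"` ending `"yx"`).
#' @param shape Override for the stored non-image dimensions, length-3
#'   integer in the order of `axes[1:3]`.
#' @param voxel_size_um Override voxel size `(z, y, x)` um.
#' @param channel_names Override channel names.
#' @return List with `stack` (5D array, canonical order) and `meta` (list:
#'   `voxel_size_um`, `channel_names`, `origin_um`, `axes_stored`).
#' @export
read_volume <- function(path, axes = NULL, shape = NULL, voxel_size_um = NULL,
                        channel_names = NULL) {
  parsed <- .read_tiff_pages(path)
  info <- if (!is.null(parsed$description)) {
    tryCatch(jsonlite::fromJSON(parsed$description), error = function(e) NULL)
  } else NULL
  axes <- axes %||% info$axes
  if (is.null(axes))
    stop("unknown axis order: file has no metadata and no 'axes' override given")
  voxel_size_um <- voxel_size_um %||% info$voxel_size_um
  if (is.null(voxel_size_um))
    stop("missing voxel size: no metadata in file and no 'voxel_size_um' override")
  ax <- strsplit(axes, "")[[1]]
  if (length(ax) != 5L || !setequal(ax, c("t", "c", "z", "y", "x")) ||
      !identical(ax[4:5], c("y", "x")))
    stop("'axes' must be a permutation of 'tczyx' ending in 'yx'")
  stored_shape <- if (!is.null(shape)) as.integer(shape) else
    as.integer(info$shape[1:3])
  if (length(stored_shape) != 3L || any(is.na(stored_shape)))
    stop("cannot determine stack shape; pass 'shape'")
  n_pages <- length(parsed$pages)
  if (prod(stored_shape) != n_pages)
    stop("declared shape implies ", prod(stored_shape), " pages but file has ",
         n_pages)
  ny <- nrow(parsed$pages[[1L]]); nx <- ncol(parsed$pages[[1L]])
  arr <- array(0, dim = c(stored_shape, ny, nx))
  d2 <- stored_shape[2L]; d3 <- stored_shape[3L]
  for (p in seq_len(n_pages)) {
    i3 <- (p - 1L) %% d3
    i2 <- ((p - 1L) %/% d3) %% d2
    i1 <- (p - 1L) %/% (d3 * d2)
    arr[i1 + 1L, i2 + 1L, i3 + 1L, , ] <- parsed$pages[[p]]
  }
  perm <- match(c("t", "c", "z"), ax)
  stack <- aperm(arr, c(perm, 4L, 5L))
  meta <- list(voxel_size_um = as.numeric(voxel_size_um),
               channel_names = channel_names %||% info$channel_names,
               origin_um = info$origin_um %||% c(0, 0, 0),
               axes_stored = axes)
  list(stack = stack, meta = meta)
}
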