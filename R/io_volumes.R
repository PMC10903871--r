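#' Multi-channel 3D image stack
#'
#' Container for a multi-channel intensity volume with anisotropic voxel
#' spacing. Data are stored as a 4D array indexed `(channel, z, y, x)`;
#' intensities are non-negative and kept in their native integer range
#' (no rescaling is ever applied).
#'
#' @param data 4D numeric array, dim `(channel, z, y, x)`, all values >= 0.
#' @param spacing_um numeric length-3, voxel edge lengths in micrometres,
#'   ordered `(z, y, x)`; all components must be positive.
#' @param channel_names optional character vector naming the channels.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, spacing_um, channel_names = NULL) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D (channel, z, y, x) array")
  if (dim(data)[1] < 1L || dim(data)[2] < 1L)
    stop("need at least 1 channel and 1 z plane")
  if (any(data < 0)) stop("intensities must be non-negative")
  spacing_um <- check_spacing(spacing_um)
  if (!is.null(channel_names) && length(channel_names) != dim(data)[1])
    stop("channel_names length must match the channel axis")
  structure(list(data = data, spacing_um = spacing_um,
                 channel_names = channel_names),
            class = "image_stack")
}

#' Integer label volume
#'
#' 3D grid of non-negative integer instance labels; 0 is background.
#'
#' @param labels 3D array of non-negative integers, dim `(z, y, x)`.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_um) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D (z, y, x) array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  structure(list(labels = labels, spacing_um = check_spacing(spacing_um)),
            class = "label_volume")
}

#' Binary foreground volume
#'
#' @param mask 3D logical array, dim `(z, y, x)`.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometres.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, spacing_um) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D (z, y, x) array")
  if (!is.logical(mask)) stop("`mask` must be logical")
  structure(list(mask = mask, spacing_um = check_spacing(spacing_um)),
            class = "binary_volume")
}

check_spacing <- function(spacing_um) {
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("spacing_um must be three positive values (z, y, x)")
  spacing_um
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d channel(s), %d x %d x %d (z,y,x), spacing %s um\n",
              d[1], d[2], d[3], d[4], paste(signif(x$spacing_um, 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d (z,y,x), %d instance(s)\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

# ---- TIFF dialect -----------------------------------------------------------
# Multi-page TIFF, one or more single-sample 16-bit pages per z plane.
# Stacks: pages ordered z-major with channels fastest (z1c1, z1c2, z2c1, ...).
# Label volumes: one page per z if max label <= 65535; otherwise each page
# carries two 16-bit samples (low word, high word), recombined on read --
# exact for labels below 2^32.

#' Read a multi-channel TIFF z-stack
#'
#' Reads a multi-page TIFF and returns an [image_stack] with the requested
#' channels ordered (nuclei, cells). Pages are assumed z-major with channels
#' fastest (the layout written by [write_stack()], and the common
#' hyperstack interleave); a single-page-per-z file is a 1-channel stack.
#'
#' @param path TIFF file path.
#' @param nuclei_channel,cells_channel 1-based channel indices in the file.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometres.
#' @param n_channels number of channels interleaved in the file (default 2,
#'   the standard nuclei + cell-marker input).
#' @return An [image_stack] with channels `(nuclei, cells)`.
#' @export
read_stack <- function(path, nuclei_channel, cells_channel, spacing_um,
                       n_channels = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  n_channels <- as.integer(n_channels)
  idx <- c(nuclei = as.integer(nuclei_channel), cells = as.integer(cells_channel))
  if (any(idx < 1L)) stop("channel indices are 1-based and must be >= 1")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) %% n_channels != 0L)
    stop("page count ", length(pages), " is not a multiple of n_channels = ", n_channels)
  if (any(idx > n_channels))
    stop("file has ", n_channels, " channel(s); requested channel ", max(idx))
  nz <- length(pages) %/% n_channels
  d <- dim(pages[[1]])
  if (length(d) != 2L) stop("expected single-sample pages for intensity stacks")
  out <- array(0, dim = c(2L, nz, d[1], d[2]))
  for (k in 1:2) {
    for (z in seq_len(nz)) {
      pg <- pages[[(z - 1L) * n_channels + idx[k]]]
      out[k, z, , ] <- decode_page(pg)
    }
  }
  image_stack(out, spacing_um, channel_names = c("nuclei", "cells"))
}

#' Write a multi-channel TIFF z-stack
#'
#' Writes 16-bit single-sample pages, z-major with channels fastest.
#' Intensities must be integers in `[0, 65535]`.
#'
#' @param path output TIFF path.
#' @param stack an [image_stack].
#' @export
write_stack <- function(path, stack) {
  stopifnot(inherits(stack, "image_stack"))
  x <- stack$data
  if (any(x != round(x)) || max(x) > 65535)
    stop("write_stack requires integer intensities in [0, 65535]")
  d <- dim(x)
  pages <- vector("list", d[1] * d[2])
  i <- 1L
  for (z in seq_len(d[2])) for (k in seq_len(d[1])) {
    pages[[i]] <- matrix(x[k, z, , ], d[3], d[4]) / 65535
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read an integer label volume from TIFF
#'
#' Single-sample pages are read directly; two-sample pages are interpreted as
#' the low/high word encoding written by [write_labels()] for labels above
#' 65535.
#'
#' @param path TIFF file path.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometres.
#' @return A [label_volume].
#' @export
read_labels <- function(path, spacing_um) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE))
  nz <- length(pages)
  d <- dim(pages[[1]])
  lab <- array(0, dim = c(nz, d[1], d[2]))
  for (z in seq_len(nz)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L && dim(pg)[3] == 2L) {
      lo <- decode_page(pg[, , 1]); hi <- decode_page(pg[, , 2])
      lab[z, , ] <- lo + 65536 * hi
    } else {
      lab[z, , ] <- decode_page(pg)
    }
  }
  label_volume(lab, spacing_um)
}

#' Write an integer label volume to TIFF
#'
#' Labels up to 65535 are written as plain 16-bit pages; larger labels use a
#' two-sample (low word, high word) 16-bit encoding that round-trips exactly
#' through [read_labels()].
#'
#' @param path output TIFF path.
#' @param vol a [label_volume].
#' @export
write_labels <- function(path, vol) {
  stopifnot(inherits(vol, "label_volume"))
  lab <- vol$labels
  d <- dim(lab)
  mx <- max(lab)
  if (mx >= 2^32) stop("labels exceed 32-bit range")
  pages <- vector("list", d[1])
  for (z in seq_len(d[1])) {
    pg <- matrix(lab[z, , ], d[2], d[3])
    if (mx <= 65535) {
      pages[[z]] <- pg / 65535
    } else {
      pages[[z]] <- array(c(pg %% 65536, pg %/% 65536) / 65535, c(d[2], d[3], 2L))
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

# readTIFF(as.is = TRUE) yields native integers for single-sample pages but
# normalized [0,1] reals once a page has extra samples; undo either way.
decode_page <- function(pg) {
  if (max(pg) <= 1 && any(pg != round(pg))) round(pg * 65535) else pg
}

#' Physical volume of an imaged region
#'
#' @param extent_um physical extents in micrometres along each axis, or a
#'   [label_volume] / [image_stack] whose grid extent is used.
#' @return Volume in cubic millimetres.
#' @examples
#' physical_volume_mm3(c(664, 664, 384))
#' @export
physical_volume_mm3 <- function(extent_um) {
  if (inherits(extent_um, "label_volume"))
    extent_um <- dim(extent_um$labels) * extent_um$spacing_um
  else if (inherits(extent_um, "image_stack"))
    extent_um <- dim(extent_um$data)[-1] * extent_um$spacing_um
  prod(as.numeric(extent_um)) / 1e9
}
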