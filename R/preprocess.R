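#' Global Otsu threshold of a 3D volume
#'
#' Computes the single threshold over the whole volume (never per slice) that
#' maximizes the between-class variance of the intensity histogram, binned
#' over the observed min--max range.
#'
#' @param channel 3D numeric array of intensities.
#' @param n_bins number of histogram bins (default 256, independent of bit
#'   depth).
#' @return The threshold intensity; the candidate set is the interior bin
#'   edges, and ties go to the smallest edge.
#' @export
otsu_threshold <- function(channel, n_bins = 256L) {
  x <- as.numeric(channel)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("constant volume: Otsu threshold is undefined")
  n_bins <- as.integer(n_bins)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / length(x)
  omega <- cumsum(p)                       # class-0 weight after bin k
  mu <- cumsum(p * (edges[-length(edges)] + diff(edges) / 2))
  mu_t <- mu[n_bins]
  # between-class variance for a split after bin k = 1..n_bins-1
  k <- seq_len(n_bins - 1L)
  w0 <- omega[k]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[k][valid])^2 / (w0[valid] * w1[valid])
  edges[which.max(sigma_b) + 1L]
}

#' Foreground mask at a threshold
#'
#' The foreground rule is at-or-above: a voxel at exactly the threshold is
#' foreground, so the foreground shrinks monotonically as the threshold rises.
#'
#' @param channel 3D numeric array.
#' @param threshold intensity threshold.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometres.
#' @return A [binary_volume].
#' @export
foreground_mask <- function(channel, threshold, spacing_um) {
  binary_volume(channel >= threshold, spacing_um)
}

#' Voxel-wise product of two channels
#'
#' Highlights candidate cell regions where nuclear and cell-marker signal
#' co-occur: the product is zero wherever either channel is zero. Computed in
#' double precision so 16-bit inputs never overflow.
#'
#' @param nuclei_channel,cells_channel 3D numeric arrays of equal shape.
#' @return 3D numeric array of products.
#' @export
channel_product <- function(nuclei_channel, cells_channel) {
  if (!identical(dim(nuclei_channel), dim(cells_channel)))
    stop("channel shapes differ")
  array(as.numeric(nuclei_channel) * as.numeric(cells_channel),
        dim = dim(nuclei_channel))
}
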