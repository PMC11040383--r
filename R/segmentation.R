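#' Segment one fluorescence channel
#'
#' Averages the channel's images, estimates the long-range illumination
#' heterogeneity with a Gaussian blur whose kernel spans half the image
#' (+/-2 sigma support = half the smaller dimension, i.e.
#' `sigma = min(dim) * blur_sigma_frac` with `blur_sigma_frac = 1/8`),
#' subtracts it, and thresholds the result with Otsu's rule. A separation
#' guard rejects the threshold when the two classes are not genuinely
#' distinct (pure-noise images yield an empty mask instead of a random
#' half-split).
#'
#' @param images `rows x cols x n` array (or list of matrices, or a single
#'   matrix) of one channel's fluorescence images.
#' @param blur_sigma_frac Background blur sigma as a fraction of the
#'   smaller image dimension.
#' @param min_separation Minimum foreground/background mean separation, in
#'   units of the background-class standard deviation, for the mask to be
#'   accepted.
#' @return Logical matrix mask.
#' @export
segment_channel <- function(images, blur_sigma_frac = 1 / 8,
                            min_separation = 4) {
  if (is.list(images)) images <- simplify2array(images)
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  n <- dim(images)[3]
  if (n == 0L || length(images) == 0L) stop("empty fluorescence stack")
  if (n < 10L)
    warning(sprintf("only %d images in channel; 10 or more are recommended", n))
  avg <- apply(images, c(1, 2), mean)
  sigma <- min(dim(avg)) * blur_sigma_frac
  bg <- EBImage::gblur(avg, sigma = sigma, boundary = "replicate")
  corr <- avg - bg
  rng <- range(corr)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(corr), ncol(corr)))
  norm <- (corr - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  mask <- norm > thr
  if (!any(mask) || all(mask)) return(matrix(FALSE, nrow(corr), ncol(corr)))
  sep <- (mean(corr[mask]) - mean(corr[!mask])) / stats::sd(corr[!mask])
  if (!is.finite(sep) || sep < min_separation)
    return(matrix(FALSE, nrow(corr), ncol(corr)))
  mask
}

#' Remove intersections between channel masks
#'
#' Pixels claimed by more than one channel (cell lines in contact) are
#' removed from every mask; the discarded fraction is reported relative to
#' the union of the original masks.
#'
#' @param masks Named list of logical matrices (>= 2 channels).
#' @return An object of class `channel_masks`: the disjoint `masks`, the
#'   `overlap_removed` map and the scalar `overlap_fraction`.
#' @export
remove_overlaps <- function(masks) {
  if (length(masks) < 2L) stop("need at least 2 channels")
  dims <- dim(masks[[1]])
  stopifnot(all(vapply(masks, function(m) identical(dim(m), dims), logical(1))))
  count <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  overlap <- count > 1L
  union_px <- sum(count > 0L)
  cleaned <- lapply(masks, function(m) m & !overlap)
  structure(
    list(masks = cleaned, overlap_removed = overlap,
         overlap_fraction = if (union_px > 0) sum(overlap) / union_px else 0),
    class = "channel_masks")
}

#' @export
print.channel_masks <- function(x, ...) {
  cat(sprintf("Channel masks (%s): %.2f%% of masked area removed as overlap\n",
              paste(names(x$masks), collapse = ", "),
              100 * x$overlap_fraction))
  invisible(x)
}

#' Distance-to-edge map of a mask
#'
#' Euclidean distance from every masked pixel to the nearest mask boundary,
#' in physical units; boundary pixels are at distance zero, the background
#' is NA. Disconnected blobs are handled independently by construction of
#' the distance transform.
#'
#' @param mask Logical matrix.
#' @param pixel_pitch um per pixel.
#' @return Numeric matrix (um), NA outside the mask.
#' @export
distance_to_edge <- function(mask, pixel_pitch = 1) {
  if (!any(mask)) stop("mask is empty")
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  out <- (pmax(dm - 1, 0)) * pixel_pitch
  out[!mask] <- NA_real_
  out
}
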