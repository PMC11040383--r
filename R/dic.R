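#' Rest reference image of a stroboscopic stack
#'
#' Averages the trailing `N_aq - N` frames, acquired after the drive has
#' stopped (no strain), into the reference image the DIC compares against.
#'
#' @param stack `rows x cols x n_frames` array.
#' @param schedule The [strobe_schedule()] of the acquisition.
#' @return Matrix with the averaged rest image.
#' @export
reference_image <- function(stack, schedule) {
  stopifnot(length(dim(stack)) == 3L)
  F <- dim(stack)[3]
  if (F != schedule$n_frames)
    stop("stack length does not match the schedule")
  if (schedule$n_frames <= schedule$n_pulses)
    stop("no rest frames: N_aq must exceed N to build a reference image")
  rest <- (schedule$n_pulses + 1L):F
  apply(stack[, , rest, drop = FALSE], c(1, 2), mean)
}

#' Block-matching digital image correlation against a reference
#'
#' Tiles the image with non-overlapping comparison boxes (`box_size` x
#' `box_size` pixels) and, for every frame, finds the integer displacement
#' maximizing the normalized cross-correlation with the reference within
#' `search_radius`, refined to sub-pixel precision by a quadratic fit around
#' the peak. Boxes without enough texture (intensity standard deviation
#' below `min_contrast`) or without a credible correlation peak are flagged
#' invalid.
#'
#' @param stack `rows x cols x n_frames` array (or a single matrix).
#' @param reference Reference matrix from [reference_image()].
#' @param box_size Odd box side in pixels (5 in the standard analysis;
#'   a 5-px box spans 2.57 um at the default pixel pitch).
#' @param search_radius Maximum displacement searched (px).
#' @param min_contrast Minimum patch intensity standard deviation.
#' @return An object of class `displacement_stack`: arrays `delta_x`,
#'   `delta_y` (`n_boxes_y x n_boxes_x x n_frames`, px), a `valid` matrix
#'   (boxes valid in every frame), and the box-centre grid (0-based px).
#' @export
dic_displacements <- function(stack, reference, box_size = 5L,
                              search_radius = 10L, min_contrast = 0.01) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  box_size <- as.integer(box_size)
  if (box_size %% 2L != 1L) stop("'box_size' must be odd")
  if (box_size > 11L) stop("'box_size' larger than 11 px is not supported")
  H <- dim(stack)[1]; W <- dim(stack)[2]; F <- dim(stack)[3]
  half <- box_size %/% 2L
  # non-overlapping grid of box centres (0-based px)
  cy <- seq(half, H - half - 1L, by = box_size)
  cx <- seq(half, W - half - 1L, by = box_size)
  nby <- length(cy); nbx <- length(cx)
  centers_r <- rep(cy, times = nbx)
  centers_c <- rep(cx, each = nby)
  dx <- array(NA_real_, c(nby, nbx, F))
  dy <- array(NA_real_, c(nby, nbx, F))
  valid <- matrix(TRUE, nby, nbx)
  for (f in seq_len(F)) {
    res <- .dic_block_match(reference, stack[, , f],
                            as.integer(centers_r), as.integer(centers_c),
                            box_size, as.integer(search_radius), min_contrast)
    dx[, , f] <- matrix(res$dx, nby, nbx)
    dy[, , f] <- matrix(res$dy, nby, nbx)
    valid <- valid & matrix(res$valid, nby, nbx)
  }
  structure(
    list(delta_x = dx, delta_y = dy, valid = valid,
         box_x = cx, box_y = cy, box_size = box_size,
         image_size = c(H, W)),
    class = "displacement_stack")
}

#' @export
print.displacement_stack <- function(x, ...) {
  cat(sprintf("DIC displacement stack: %d x %d boxes (%d px) x %d frames, %.1f%% valid\n",
              length(x$box_y), length(x$box_x), x$box_size,
              dim(x$delta_x)[3], 100 * mean(x$valid)))
  invisible(x)
}

#' Homodyne displacement maps from a DIC displacement stack
#'
#' Projects each box's displacement time series onto the carrier frequency,
#' yielding per-box complex displacement phasors (amplitude and phase maps).
#' Boxes flagged invalid in any frame propagate as invalid (NA).
#'
#' @param dstack A [dic_displacements()] result.
#' @param schedule The [strobe_schedule()] of the acquisition.
#' @param f0 Carrier frequency (Hz).
#' @param pixel_pitch Pixel pitch (um/px); maps are returned in um.
#' @return An object of class `homodyne_displacement_map` with complex
#'   matrices `delta_x`, `delta_y` (um), the box grid, and metadata.
#' @export
homodyne_displacement <- function(dstack, schedule, f0, pixel_pitch = 1) {
  stopifnot(inherits(dstack, "displacement_stack"))
  F <- dim(dstack$delta_x)[3]
  if (F < schedule$n_pulses)
    stop("need at least N frames for the homodyne projection")
  tt <- schedule$sample_times[seq_len(F)]
  nby <- dim(dstack$delta_x)[1]; nbx <- dim(dstack$delta_x)[2]
  flat <- function(a) matrix(aperm(a, c(3, 1, 2)), nrow = F)
  vx <- flat(dstack$delta_x); vy <- flat(dstack$delta_y)
  bad <- !as.vector(dstack$valid)
  vx[, bad] <- 0; vy[, bad] <- 0   # placeholder; re-flagged below
  hx <- homodyne_coefficient(vx, tt, f0) * pixel_pitch
  hy <- homodyne_coefficient(vy, tt, f0) * pixel_pitch
  hx[bad] <- NA_complex_; hy[bad] <- NA_complex_
  structure(
    list(delta_x = matrix(hx, nby, nbx), delta_y = matrix(hy, nby, nbx),
         box_x = dstack$box_x, box_y = dstack$box_y,
         box_size = dstack$box_size, pixel_pitch = pixel_pitch,
         f0 = f0, image_size = dstack$image_size),
    class = "homodyne_displacement_map")
}

#' @export
print.homodyne_displacement_map <- function(x, ...) {
  amp <- sqrt(Mod(x$delta_x)^2 + Mod(x$delta_y)^2)
  cat(sprintf("Homodyne displacement map: %d x %d boxes, median |delta_H| = %.3g um\n",
              nrow(x$delta_x), ncol(x$delta_x),
              stats::median(amp, na.rm = TRUE)))
  invisible(x)
}

#' Resample a complex map into fluorescence coordinates
#'
#' Applies a 2x3 affine transform mapping fluorescence pixel coordinates to
#' fast-camera coordinates and resamples the map by bilinear interpolation
#' (real and imaginary parts independently), establishing pixel-to-pixel
#' correspondence between the two imaging systems.
#'
#' @param map Complex (or numeric) matrix in fast-camera coordinates, with
#'   optional attributes; here interpreted on its own pixel grid (0-based).
#' @param affine 2x3 matrix `A` such that fast-camera `(x, y)' = A %*%
#'   (x_f, y_f, 1)'` for fluorescence coordinates `(x_f, y_f)` (0-based).
#' @param out_size `c(rows, cols)` of the output grid; defaults to the
#'   input size.
#' @return Matrix of the resampled map on the fluorescence grid.
#' @export
warp_to_fluorescence <- function(map, affine = diag(1, 2, 3),
                                 out_size = dim(map)) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(2, 3)))
  if (abs(det(affine[, 1:2])) < 1e-12)
    stop("singular affine transform")
  Ho <- out_size[1]; Wo <- out_size[2]
  xf <- rep(0:(Wo - 1), each = Ho)
  yf <- rep(0:(Ho - 1), Wo)
  src <- affine %*% rbind(xf, yf, 1)
  out <- bilinear_sample_cplx(map, src[2, ] + 1, src[1, ] + 1)
  matrix(out, Ho, Wo)
}
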