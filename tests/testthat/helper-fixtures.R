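# Shared fixture builders. Everything is generated in code at test time.

# Exact sub-pixel shift of a periodic image via the Fourier shift theorem
# (the independent oracle for sub-pixel DIC checks).
fourier_shift <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  kx <- c(0:(W %/% 2), -((ceiling(W / 2) - 1):1)) / W
  ky <- c(0:(H %/% 2), -((ceiling(H / 2) - 1):1)) / H
  ph <- exp(-2i * pi * outer(ky * dy, kx * dx, "+"))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (H * W)
}

# A textured reference image without cells or beads.
speckle_image <- function(size = 96L, contrast = 0.12, seed = 2L) {
  sc <- scene_spec(image_size = c(size, size), cells = list(), n_beads = 0L,
                   bead_xy = data.frame(x = numeric(0), y = numeric(0)),
                   seed = seed)
  render_texture(sc, background_contrast = contrast)
}

# A scene with cells laid out on a grid, each with a prescribed modulus.
grid_scene <- function(G_values, size = 400L, channel = "green", seed = 9L,
                       flow_u = 1.0 * exp(0.3i) * c(x = cos(pi / 6), y = sin(pi / 6)),
                       soft_center_factor = 1) {
  n <- length(G_values)
  ng <- ceiling(sqrt(n))
  sp <- size / ng
  cells <- lapply(seq_len(n), function(i) {
    ix <- (i - 1) %% ng; iy <- (i - 1) %/% ng
    cell_spec(center = c((ix + 0.5) * sp, (iy + 0.5) * sp),
              axes = c(0.42, 0.38) * sp, angle = (i %% 7) * 0.4,
              channel = channel, G = G_values[i],
              soft_center_factor = soft_center_factor)
  })
  scene_spec(image_size = c(size, size), cells = cells, n_beads = 40L,
             flow_u = flow_u, seed = seed)
}

# Sample the ground-truth displacement of a scene on the DIC-box grid as a
# homodyne displacement map (um), bypassing imaging entirely.
truth_displacement_map <- function(scene, box_size = 5L) {
  gt <- ground_truth_displacement(scene)
  H <- scene$image_size[1]; W <- scene$image_size[2]
  half <- box_size %/% 2
  by <- seq(half, H - half - 1L, by = box_size)
  bx <- seq(half, W - half - 1L, by = box_size)
  structure(
    list(delta_x = gt$delta_x[by + 1, bx + 1] * 1e6,
         delta_y = gt$delta_y[by + 1, bx + 1] * 1e6,
         box_x = bx, box_y = by, box_size = box_size,
         pixel_pitch = scene$pixel_pitch, f0 = 30e3,
         image_size = c(H, W)),
    class = "homodyne_displacement_map")
}

# Boxes whose 3x3 box-neighbourhood lies inside a single cell (so central
# differences never straddle a boundary), on the grid of `dmap`.
interior_boxes <- function(scene, dmap) {
  inst <- scene_masks(scene)$instance[dmap$box_y + 1, dmap$box_x + 1]
  nby <- nrow(inst); nbx <- ncol(inst)
  out <- matrix(FALSE, nby, nbx)
  for (i in 2:(nby - 1)) for (j in 2:(nbx - 1)) {
    nb <- inst[(i - 1):(i + 1), (j - 1):(j + 1)]
    out[i, j] <- inst[i, j] > 0 && all(nb == inst[i, j])
  }
  out
}

# A displacement_stack with one sinusoidal time series per box (unit test
# input for the homodyne map, bypassing the block matcher).
tone_displacement_stack <- function(amp_x, amp_y, schedule, f0,
                                    nby = 4L, nbx = 4L, offset = 0) {
  F <- schedule$n_frames
  tt <- schedule$sample_times
  s <- sin(2 * pi * f0 * tt)
  dx <- array(0, c(nby, nbx, F)); dy <- array(0, c(nby, nbx, F))
  for (n in seq_len(F)) {
    dx[, , n] <- amp_x * s[n] + offset
    dy[, , n] <- amp_y * s[n] + offset
  }
  structure(
    list(delta_x = dx, delta_y = dy,
         valid = matrix(TRUE, nby, nbx),
         box_x = (seq_len(nbx) - 1L) * 5L + 2L,
         box_y = (seq_len(nby) - 1L) * 5L + 2L,
         box_size = 5L, image_size = c(nby * 5L, nbx * 5L)),
    class = "displacement_stack")
}

# Synthetic oscillating bead centroid lists for the linking/homodyne tests.
oscillating_centroids <- function(base_xy, amp_px, schedule, f0,
                                  phase = 0, amp_y_px = 0) {
  tt <- schedule$sample_times
  lapply(seq_along(tt), function(n) {
    s <- sin(2 * pi * f0 * tt[n] + phase)
    data.frame(x = base_xy$x + amp_px * s, y = base_xy$y + amp_y_px * s)
  })
}
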