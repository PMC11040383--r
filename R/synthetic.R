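#' Specify one synthetic cell
#'
#' Cells are elliptical patches of phase-contrast-like speckle texture with a
#' prescribed complex dynamic shear modulus. The modulus may soften towards
#' the cell centre (as observed near nuclei) via `soft_center_factor`.
#'
#' @param center Cell centre, `c(x, y)` in pixels (0-based).
#' @param axes Ellipse semi-axes `c(a, b)` in pixels.
#' @param angle Ellipse orientation (radians).
#' @param channel Fluorescence channel label (e.g. `"green"`, `"orange"`).
#' @param G Complex dynamic shear modulus at the cell edge (Pa);
#'   `G = G' + iG''`.
#' @param soft_center_factor Ratio edge-modulus / centre-modulus (>= 1);
#'   1 gives a uniform cell.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(center, axes, angle = 0, channel = "green",
                      G = complex(real = 5000, imaginary = 5000),
                      soft_center_factor = 1) {
  stopifnot(length(center) == 2L, length(axes) == 2L, all(axes > 0),
            soft_center_factor >= 1)
  if (Mod(G) <= 0) stop("|G| must be positive inside the cell")
  structure(list(center = as.numeric(center), axes = as.numeric(axes),
                 angle = angle, channel = channel, G = as.complex(G),
                 soft_center_factor = soft_center_factor),
            class = "cell_spec")
}

#' Specify a synthetic mechanotyping scene
#'
#' Defines everything the forward model needs: the imaging geometry, the
#' cells with their ground-truth moduli, the tracer beads, the oscillating
#' flow the transducer drives in the fluid gap, and the camera noise.
#' The flow is prescribed (the transducer physics is not modelled) as a
#' spatially uniform complex velocity phasor at the bead height.
#'
#' @param image_size `c(rows, cols)` of the fast-camera frames (pixels).
#' @param pixel_pitch Fast-camera pixel pitch (um/px); the default 0.514
#'   makes a 5-px DIC box span 2.57 um.
#' @param cells List of [cell_spec()] objects.
#' @param n_beads Number of tracer beads (placed by the generator unless
#'   `bead_xy` is given).
#' @param bead_xy Optional data.frame with columns `x`, `y` (0-based px).
#' @param bead_radius_um Tracer bead radius `R_b` (um).
#' @param flow_u Complex velocity phasor at `z = R_b`, `c(x = , y = )` (m/s).
#' @param mu Dynamic viscosity of the medium (Pa s); water at room
#'   temperature by default.
#' @param noise_sigma Additive Gaussian camera noise (fraction of full
#'   scale; images are rendered on a 0..1 scale).
#' @param seed RNG seed controlling textures, bead placement and noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(256L, 256L), pixel_pitch = 0.514,
                       cells = list(), n_beads = 30L, bead_xy = NULL,
                       bead_radius_um = 1.5,
                       flow_u = c(x = 0.5 + 0i, y = 0.25 + 0i),
                       mu = 1.0e-3, noise_sigma = 0.005, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16),
            pixel_pitch > 0, bead_radius_um > 0, mu > 0, noise_sigma >= 0)
  flow_u <- as.complex(flow_u)
  if (length(flow_u) != 2L) stop("'flow_u' must hold an x and a y phasor")
  names(flow_u) <- c("x", "y")
  sc <- structure(
    list(image_size = as.integer(image_size), pixel_pitch = pixel_pitch,
         cells = cells, n_beads = as.integer(n_beads),
         bead_radius_um = bead_radius_um, flow_u = flow_u, mu = mu,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "scene_spec")
  sc$bead_xy <- if (is.null(bead_xy)) place_beads(sc) else bead_xy
  sc
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d px (%.3f um/px), %d cells, %d beads\n",
              x$image_size[1], x$image_size[2], x$pixel_pitch,
              length(x$cells), nrow(x$bead_xy)))
  if (length(x$cells)) {
    g <- vapply(x$cells, function(cc) Mod(cc$G), numeric(1))
    cat(sprintf("  |G_true| range: %.2f - %.2f kPa\n",
                min(g) / 1e3, max(g) / 1e3))
  }
  cat(sprintf("  flow |u| = (%.3g, %.3g) m/s, mu = %g Pa s, R_b = %g um\n",
              Mod(x$flow_u[1]), Mod(x$flow_u[2]), x$mu, x$bead_radius_um))
  invisible(x)
}

# Uniformly scattered beads with a minimum separation (rejection sampling).
place_beads <- function(scene) {
  H <- scene$image_size[1]; W <- scene$image_size[2]
  min_sep <- max(12, 0.7 * sqrt(H * W / max(scene$n_beads, 1)))
  with_seed(scene$seed + 101L, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < scene$n_beads && tries < 20000L) {
      tries <- tries + 1L
      x <- stats::runif(1, 8, W - 9); y <- stats::runif(1, 8, H - 9)
      if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    data.frame(x = xs, y = ys)
  })
}

# Elliptical radius rho (rho <= 1 inside) of pixel grid points for a cell.
cell_rho <- function(cell, xg, yg) {
  dx <- xg - cell$center[1]; dy <- yg - cell$center[2]
  ca <- cos(cell$angle); sa <- sin(cell$angle)
  u <- (dx * ca + dy * sa) / cell$axes[1]
  v <- (-dx * sa + dy * ca) / cell$axes[2]
  sqrt(u * u + v * v)
}

#' Ground-truth geometric masks of a scene
#'
#' @param scene A [scene_spec()].
#' @return List with `instance` (integer matrix, 0 = background, i = cell
#'   index) and `channel` (named list of logical matrices).
#' @export
scene_masks <- function(scene) {
  H <- scene$image_size[1]; W <- scene$image_size[2]
  xg <- matrix(rep(0:(W - 1), each = H), H, W)
  yg <- matrix(rep(0:(H - 1), W), H, W)
  inst <- matrix(0L, H, W)
  inside <- lapply(scene$cells, function(cc) cell_rho(cc, xg, yg) <= 1)
  for (i in seq_along(inside)) inst[inside[[i]]] <- i
  chans <- unique(vapply(scene$cells, `[[`, character(1), "channel"))
  ch <- lapply(chans, function(cn) {
    ids <- which(vapply(scene$cells, function(cc) cc$channel == cn, logical(1)))
    Reduce(`|`, inside[ids], matrix(FALSE, H, W))
  })
  names(ch) <- chans
  list(instance = inst, channel = ch)
}

#' Uniform wall shear-stress phasors of a scene
#'
#' Applies the linear-gradient stress law `sigma_k = mu * u_k / R_b` to the
#' scene's prescribed velocity phasor.
#'
#' @param scene A [scene_spec()].
#' @return Named complex vector `c(x = , y = )` (Pa).
#' @export
scene_stress_true <- function(scene) {
  scene$mu * scene$flow_u / (scene$bead_radius_um * 1e-6)
}

#' Ground-truth oscillating displacement field of the cells
#'
#' Constructs, per cell, the complex displacement phasor field whose spatial
#' gradients invert analytically to the cell's prescribed modulus under the
#' pure/simple shear compliance relations used by the analysis
#' (`1/G_p = (1/sigma_x) d(delta_x)/dx + (1/sigma_y) d(delta_y)/dy`,
#' `1/G_s = (1/sigma_x) d(delta_x)/dy + (1/sigma_y) d(delta_y)/dx`,
#' `G = (G_p + G_s)/2`). For a uniform cell the field is affine in position;
#' for a soft-centred cell the local compliance is integrated numerically.
#' Outside the cells the field decays to zero over a few pixels.
#'
#' @param scene A [scene_spec()].
#' @param stress_threshold Relative magnitude below which a stress component
#'   is considered absent (matching the analysis default).
#' @return List with complex matrices `delta_x`, `delta_y` (metres), the
#'   per-pixel complex modulus map `G_map` (NA outside cells) and the
#'   instance mask.
#' @export
ground_truth_displacement <- function(scene, stress_threshold = 0.1) {
  H <- scene$image_size[1]; W <- scene$image_size[2]
  sig <- scene_stress_true(scene)
  smax <- max(Mod(sig))
  if (smax == 0 && length(scene$cells))
    stop("zero stress with nonzero G_true requested")
  valid <- Mod(sig) >= stress_threshold * smax
  nv <- sum(valid)
  w <- ifelse(valid, 1 / nv, 0)          # compliance-term weights
  h_m <- scene$pixel_pitch * 1e-6        # metres per pixel

  dx_map <- matrix(0 + 0i, H, W)
  dy_map <- matrix(0 + 0i, H, W)
  G_map <- matrix(NA_complex_, H, W)
  inst <- scene_masks(scene)$instance
  taper_px <- 4

  for (i in seq_along(scene$cells)) {
    cell <- scene$cells[[i]]
    ext <- max(cell$axes) + 3 * taper_px
    rows <- max(1, floor(cell$center[2] - ext)):min(H, ceiling(cell$center[2] + ext) + 1)
    cols <- max(1, floor(cell$center[1] - ext)):min(W, ceiling(cell$center[1] + ext) + 1)
    xg <- matrix(rep(cols - 1, each = length(rows)), length(rows))
    yg <- matrix(rep(rows - 1, length(cols)), length(rows))
    rho <- cell_rho(cell, xg, yg)
    s <- cell$soft_center_factor
    Jloc <- (1 + (s - 1) * pmax(1 - pmin(rho, 1)^2, 0)) / cell$G
    inside <- rho <= 1
    G_map[rows, cols][inside] <- (1 / Jloc)[inside]

    if (s == 1) {
      lin <- ((xg - cell$center[1]) + (yg - cell$center[2])) * h_m
      base_x <- sig[["x"]] * w[1] * Jloc * lin
      base_y <- sig[["y"]] * w[2] * Jloc * lin
    } else {
      # integrate the local compliance from the cell centre along x and y
      cum_x <- cumint(Jloc, along = "x", origin = cell$center[1] - (cols[1] - 1) + 1) * h_m
      cum_y <- cumint(Jloc, along = "y", origin = cell$center[2] - (rows[1] - 1) + 1) * h_m
      base_x <- sig[["x"]] * w[1] * (cum_x + cum_y)
      base_y <- sig[["y"]] * w[2] * (cum_x + cum_y)
    }
    taper <- exp(-(pmax(rho - 1, 0) * min(cell$axes) / taper_px)^2)
    dx_map[rows, cols] <- dx_map[rows, cols] + base_x * taper
    dy_map[rows, cols] <- dy_map[rows, cols] + base_y * taper
  }
  list(delta_x = dx_map, delta_y = dy_map, G_map = G_map, instance = inst)
}

# Cumulative integral of matrix J along x (columns) or y (rows) from a
# fractional origin index (1-based, in the sub-grid). Trapezoidal; exact
# (linear result) for constant J.
cumint <- function(J, along = c("x", "y"), origin) {
  along <- match.arg(along)
  if (along == "y") return(t(cumint(t(J), "x", origin)))
  nc <- ncol(J)
  S <- J
  S[, 1] <- 0
  if (nc > 1) {
    inc <- (J[, -1] + J[, -nc]) / 2
    S[, -1] <- t(apply(inc, 1, cumsum))
  }
  # reference value at the (fractional) origin column, per row
  o <- min(max(origin, 1), nc)
  o0 <- floor(o); fo <- o - o0
  Sref <- if (o0 >= nc) S[, nc] else S[, o0] * (1 - fo) + S[, o0 + 1] * fo
  S - matrix(Sref, nrow(J), nc)
}

# Band-passed speckle texture on a pixel grid (phase-contrast-like local
# contrast for the DIC to lock onto).
speckle <- function(H, W, blur_lo = 1.3, blur_hi = 4, contrast = 0.12) {
  z <- matrix(stats::rnorm(H * W), H, W)
  lo <- EBImage::gblur(z, sigma = blur_lo)
  hi <- EBImage::gblur(z, sigma = blur_hi)
  b <- lo - hi
  b * (contrast / stats::sd(b))
}

#' Rest texture of the fast-camera field of view
#'
#' Background dish speckle (faint) plus stronger per-cell speckle, on a
#' 0..1 intensity scale. Deterministic given the scene seed.
#'
#' @param scene A [scene_spec()].
#' @param cell_contrast,background_contrast Texture standard deviations.
#' @return Matrix `image_size` with the rest (undeformed) image.
#' @export
render_texture <- function(scene, cell_contrast = 0.12,
                           background_contrast = 0.06) {
  H <- scene$image_size[1]; W <- scene$image_size[2]
  masks <- scene_masks(scene)
  with_seed(scene$seed + 7L, {
    img <- 0.5 + speckle(H, W, contrast = background_contrast)
    if (length(scene$cells)) {
      cs <- speckle(H, W, contrast = cell_contrast)
      sel <- masks$instance > 0
      img[sel] <- 0.5 + cs[sel]
    }
    img
  })
}

#' Render the stroboscopic fast-camera acquisition
#'
#' Produces the two fast-camera stacks of a synthetic experiment: the cell
#' (phase-contrast) stack, in which the rest texture is warped each frame by
#' the instantaneous cell displacement, and the bead stack, in which dark
#' tracer discs are advected by the prescribed fluid flow. Frame `n`
#' (reconstructed time `t_n`) carries the oscillation
#' `Re[delta * exp(2i pi f0 t_n)]` scaled by the Gaussian pulse envelope at
#' the in-period sampling time; the trailing `N_aq - N` frames are at rest.
#' Additive Gaussian camera noise is applied to both stacks.
#'
#' @param scene A [scene_spec()].
#' @param schedule A [strobe_schedule()].
#' @param config The [pulse_train_config()] consistent with `schedule`.
#' @return List with arrays `cells` and `beads` (`rows x cols x n_frames`),
#'   the envelope per frame, the ground-truth bead tracks (`frame`, `id`,
#'   `x_px`, `y_px`) and the ground-truth displacement object.
#' @export
render_strobe_stack <- function(scene, schedule, config) {
  stopifnot(inherits(schedule, "strobe_schedule"),
            inherits(config, "pulse_train_config"))
  if (schedule$n_pulses != config$n_pulses)
    stop("schedule inconsistent with config")
  H <- scene$image_size[1]; W <- scene$image_size[2]
  h_m <- scene$pixel_pitch * 1e-6
  gt <- ground_truth_displacement(scene)
  dpx_x <- gt$delta_x / h_m
  dpx_y <- gt$delta_y / h_m

  omega <- 2 * pi * config$f0
  tt <- schedule$sample_times
  driven <- seq_along(tt) <= schedule$n_pulses
  env <- ifelse(driven, pulse_envelope(config, tt), 0)
  phase <- exp(1i * omega * tt)

  # fluid displacement phasor at bead height, in pixels
  dflu_px <- (scene$flow_u / (1i * omega)) / h_m
  amp_max <- max(Mod(dpx_x) + Mod(dpx_y), Mod(dflu_px[1]) + Mod(dflu_px[2]))
  if (amp_max > min(H, W) / 2)
    stop("displacement amplitude exceeds half the image; reduce the drive")

  tex <- render_texture(scene)
  F <- schedule$n_frames
  cells <- array(0, c(H, W, F))
  beads <- array(0, c(H, W, F))
  rows0 <- matrix(rep(seq_len(H), W), H, W)
  cols0 <- matrix(rep(seq_len(W), each = H), H, W)
  r_px <- scene$bead_radius_um / scene$pixel_pitch
  bx <- scene$bead_xy$x; by <- scene$bead_xy$y
  nb <- length(bx)
  tracks <- vector("list", F)

  with_seed(scene$seed + 23L, {
    for (n in seq_len(F)) {
      m <- env[n] * phase[n]
      dx <- Re(dpx_x * m); dy <- Re(dpx_y * m)
      cells[, , n] <- matrix(
        bicubic_sample(tex, rows0 - dy, cols0 - dx), H, W) +
        stats::rnorm(H * W, sd = scene$noise_sigma)
      bdx <- Re(dflu_px[["x"]] * m); bdy <- Re(dflu_px[["y"]] * m)
      frame <- matrix(0.6, H, W)
      for (b in seq_len(nb))
        frame <- draw_disc(frame, bx[b] + bdx, by[b] + bdy, r_px, 0.4)
      beads[, , n] <- frame + stats::rnorm(H * W, sd = scene$noise_sigma)
      tracks[[n]] <- data.frame(frame = n, id = seq_len(nb),
                                x_px = bx + bdx, y_px = by + bdy)
    }
  })
  list(cells = cells, beads = beads, envelope = env,
       times = tt, truth_tracks = do.call(rbind, tracks), truth = gt)
}

# Draw one anti-aliased dark disc (centre 0-based px) into an image.
draw_disc <- function(img, cx, cy, r, depth) {
  H <- nrow(img); W <- ncol(img)
  rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r) + 2)
  cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r) + 2)
  dy <- (rows - 1) - cy; dx <- (cols - 1) - cx
  d <- sqrt(outer(dy^2, dx^2, "+"))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  img[rows, cols] <- img[rows, cols] - depth * cov
  img
}

#' Render fluorescence channel stacks
#'
#' Each channel images its cells as bright patches over a dark background,
#' under a smooth long-range illumination heterogeneity (broad Gaussian
#' ramp), with independent per-image camera noise. Cells overlapping in
#' space but labelled in different channels appear bright in both.
#'
#' @param scene A [scene_spec()].
#' @param n_images Images per channel (the analysis averages them).
#' @param background_amplitude Peak amplitude of the illumination ramp.
#' @param noise_sd Per-image Gaussian noise.
#' @return Named list (one entry per channel) of `rows x cols x n_images`
#'   arrays.
#' @export
render_fluorescence <- function(scene, n_images = 10L,
                                background_amplitude = 0.2,
                                noise_sd = 0.02) {
  H <- scene$image_size[1]; W <- scene$image_size[2]
  masks <- scene_masks(scene)$channel
  xg <- matrix(rep(0:(W - 1), each = H), H, W)
  yg <- matrix(rep(0:(H - 1), W), H, W)
  illum <- background_amplitude *
    exp(-((xg - W / 3)^2 + (yg - H / 4)^2) / (2 * (0.7 * max(H, W))^2))
  with_seed(scene$seed + 57L, {
    out <- lapply(masks, function(msk) {
      base <- 0.05 + 0.65 * msk + illum
      arr <- array(0, c(H, W, n_images))
      for (k in seq_len(n_images))
        arr[, , k] <- base + stats::rnorm(H * W, sd = noise_sd)
      arr
    })
    out
  })
}

#' Run the full forward model of one experiment
#'
#' Convenience wrapper producing everything [run_pipeline()] consumes:
#' strobe schedule, fast-camera cell and bead stacks, fluorescence stacks,
#' and the ground truth (displacement phasors, modulus map, bead tracks).
#'
#' @param scene A [scene_spec()].
#' @param config A [pulse_train_config()]; defaults to the 30 kHz carrier,
#'   10 kHz envelope study configuration.
#' @param n_fluo Images per fluorescence channel.
#' @return An object of class `strobomech_sim`.
#' @export
simulate_experiment <- function(scene,
                                config = pulse_train_config(
                                  f0 = 30e3, alpha = 10e3,
                                  n_pulses = 250L),
                                n_fluo = 10L) {
  schedule <- strobe_schedule(config)
  stk <- render_strobe_stack(scene, schedule, config)
  fluo <- render_fluorescence(scene, n_images = n_fluo)
  structure(
    list(scene = scene, config = config, schedule = schedule,
         cells = stk$cells, beads = stk$beads, fluorescence = fluo,
         envelope = stk$envelope, truth = stk$truth,
         truth_tracks = stk$truth_tracks),
    class = "strobomech_sim")
}

#' @export
print.strobomech_sim <- function(x, ...) {
  cat("Synthetic stroboscopic experiment\n")
  print(x$scene)
  print(x$config)
  invisible(x)
}

#' The default two-population study scene
#'
#' A co-culture-like scene with two cell populations of distinct median
#' dynamic modulus (4.4 kPa "green" and 6.3 kPa "orange"), loss tangent
#' near 1 (storage and loss moduli comparable), lognormal cell-to-cell
#' spread rescaled so the realized population medians equal the nominal
#' values exactly, and tracer beads advected by a uniform oscillating flow
#' of 0.56 m/s magnitude at the bead height.
#'
#' @param image_size Frame size in pixels.
#' @param n_per_pop Cells per population.
#' @param median_G_kPa Nominal |G| medians (kPa) of the two populations.
#' @param sdlog Lognormal spread of cell |G| around the population median.
#' @param phase_sd Spread of the loss angle around `pi/4` (radians).
#' @param soft_center_factor Edge/centre modulus ratio applied to every
#'   cell (1 = uniform cells).
#' @param noise_sigma Fast-camera noise (0..1 scale).
#' @param seed RNG seed.
#' @return A [scene_spec()].
#' @export
two_population_scene <- function(image_size = c(320L, 320L), n_per_pop = 8L,
                                 median_G_kPa = c(green = 4.4, orange = 6.3),
                                 sdlog = 0.25, phase_sd = 0.15,
                                 soft_center_factor = 1,
                                 noise_sigma = 0.005, seed = 42L) {
  H <- image_size[1]; W <- image_size[2]
  n_tot <- 2L * n_per_pop
  with_seed(seed, {
    # jittered grid placement, populations interleaved
    ng <- ceiling(sqrt(n_tot))
    gx <- (rep(seq_len(ng), times = ng) - 0.5) * (W / ng)
    gy <- (rep(seq_len(ng), each = ng) - 0.5) * (H / ng)
    ord <- sample(ng * ng)[seq_len(n_tot)]
    jit <- W / ng * 0.1
    cx <- gx[ord] + stats::runif(n_tot, -jit, jit)
    cy <- gy[ord] + stats::runif(n_tot, -jit, jit)
    # keep neighbouring cells disjoint even at worst-case jitter
    rmax <- min(W / ng, H / ng) / 2 - jit - 3
    pop <- rep(names(median_G_kPa), each = n_per_pop)
    cells <- vector("list", n_tot)
    for (p in names(median_G_kPa)) {
      idx <- which(pop == p)
      z <- stats::rnorm(length(idx), sd = sdlog)
      gmod <- median_G_kPa[[p]] * 1e3 * exp(z - stats::median(z))
      gphi <- pi / 4 + stats::rnorm(length(idx), sd = phase_sd)
      for (k in seq_along(idx)) {
        a <- stats::runif(1, 0.78, 1) * rmax
        b <- stats::runif(1, 0.78, 1) * rmax
        cells[[idx[k]]] <- cell_spec(
          center = c(cx[idx[k]], cy[idx[k]]), axes = c(a, b),
          angle = stats::runif(1, 0, pi), channel = p,
          G = gmod[k] * exp(1i * gphi[k]),
          soft_center_factor = soft_center_factor)
      }
    }
    scene_spec(image_size = image_size, cells = cells,
               n_beads = max(48L, ceiling(n_tot * 3)),
               flow_u = 1.0 * exp(0.3i) * c(x = cos(pi / 6), y = sin(pi / 6)),
               noise_sigma = noise_sigma, seed = seed)
  })
}
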