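#' Detect tracer beads in one frame
#'
#' Tracer beads appear as dark circular dots on a brighter background. The
#' frame is inverted, thresholded robustly against the background level, and
#' connected components of plausible area are reduced to intensity-weighted
#' sub-pixel centroids. Detections closer than one bead radius are merged.
#'
#' @param frame Grayscale matrix (0..1 scale).
#' @param radius_px Approximate bead radius in pixels.
#' @param min_depth Minimum contrast (below background) a bead must have.
#' @return data.frame with columns `x`, `y` (0-based pixel coordinates,
#'   x = column, y = row); zero rows if nothing is found.
#' @export
detect_beads <- function(frame, radius_px = 3, min_depth = 0.1) {
  bg <- stats::median(frame)
  inv <- pmax(bg - frame, 0)
  bw <- inv > min_depth / 2
  if (!any(bw)) return(data.frame(x = numeric(0), y = numeric(0)))
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  area_lo <- 0.3 * pi * radius_px^2
  xs <- ys <- numeric(0)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- (idx - 1) %% nrow(frame) + 1
  cols <- (idx - 1) %/% nrow(frame) + 1
  wts <- inv[idx]
  for (l in seq_len(n)) {
    sel <- labs == l
    if (sum(sel) < area_lo) next
    if (max(wts[sel]) < min_depth) next
    w <- wts[sel]
    xs <- c(xs, sum((cols[sel] - 1) * w) / sum(w))
    ys <- c(ys, sum((rows[sel] - 1) * w) / sum(w))
  }
  # merge duplicates within one radius
  keep <- rep(TRUE, length(xs))
  if (length(xs) > 1) {
    for (i in seq_along(xs)) {
      if (!keep[i]) next
      d <- sqrt((xs - xs[i])^2 + (ys - ys[i])^2)
      close_ids <- which(d < radius_px & seq_along(xs) > i)
      if (length(close_ids)) {
        xs[i] <- mean(c(xs[i], xs[close_ids]))
        ys[i] <- mean(c(ys[i], ys[close_ids]))
        keep[close_ids] <- FALSE
      }
    }
  }
  data.frame(x = xs[keep], y = ys[keep])
}

#' Link per-frame detections into particle tracks
#'
#' Nearest-neighbour linking with a maximum-jump threshold below half the
#' median inter-particle distance, so that the oscillatory displacements
#' stay unambiguous (displacements must be smaller than inter-distances).
#' If two candidates fall within the threshold of one particle the link is
#' ambiguous: the particle's track is terminated and the event counted.
#' Tracks not covering every frame are flagged incomplete.
#'
#' @param centroids List of per-frame data.frames as from [detect_beads()].
#' @param max_jump Maximum linking distance (px); default half the median
#'   nearest-neighbour distance in the first frame.
#' @return An object of class `track_set`: data.frame (`frame`, `id`, `x`,
#'   `y`) with attributes `complete` (named logical per id) and
#'   `n_ambiguous`.
#' @export
link_tracks <- function(centroids, max_jump = NULL) {
  nf <- length(centroids)
  stopifnot(nf >= 1L)
  first <- centroids[[1]]
  if (is.null(max_jump)) {
    if (nrow(first) > 1) {
      d <- as.matrix(stats::dist(first))
      diag(d) <- Inf
      max_jump <- stats::median(apply(d, 1, min)) / 2
    } else max_jump <- Inf
  }
  next_id <- nrow(first)
  cur <- if (next_id) data.frame(id = seq_len(next_id), x = first$x, y = first$y)
         else data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  out <- list(cbind(frame = 1L, cur[, c("id", "x", "y")]))
  n_amb <- 0L
  for (f in seq_len(nf - 1L)) {
    nxt <- centroids[[f + 1L]]
    rows <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
    used <- rep(FALSE, nrow(nxt))
    if (nrow(cur) && nrow(nxt)) {
      for (i in seq_len(nrow(cur))) {
        d <- sqrt((nxt$x - cur$x[i])^2 + (nxt$y - cur$y[i])^2)
        d[used] <- Inf
        cand <- which(d <= max_jump)
        if (length(cand) == 1L) {
          used[cand] <- TRUE
          rows <- rbind(rows, data.frame(id = cur$id[i],
                                         x = nxt$x[cand], y = nxt$y[cand]))
        } else if (length(cand) > 1L) {
          n_amb <- n_amb + 1L   # ambiguous: drop the link, end the track
        }
      }
    }
    if (any(!used)) {
      fresh <- which(!used)
      rows <- rbind(rows, data.frame(id = next_id + seq_along(fresh),
                                     x = nxt$x[fresh], y = nxt$y[fresh]))
      next_id <- next_id + length(fresh)
    }
    out[[f + 1L]] <- cbind(frame = f + 1L, rows)
    cur <- rows
  }
  tr <- do.call(rbind, out)
  counts <- table(factor(tr$id, levels = seq_len(max(next_id, 1))))
  complete <- as.vector(counts) == nf
  names(complete) <- names(counts)
  structure(tr, class = c("track_set", "data.frame"),
            complete = complete, n_frames = nf, n_ambiguous = n_amb,
            max_jump = max_jump)
}

#' Complete-track ids of a track set
#' @param tracks A `track_set`.
#' @return Integer vector of ids present in every frame.
#' @export
complete_ids <- function(tracks) {
  cp <- attr(tracks, "complete")
  as.integer(names(cp)[cp])
}

#' Homodyne oscillating flow field from bead tracks
#'
#' The field of view is divided into an `n x n` grid of sub-FOVs, `n` chosen
#' as the largest order for which every sub-FOV holds at least five complete
#' tracks. Within each sub-FOV the bead displacements (about each track's
#' mean position) are averaged over particles per direction, the homodyne
#' coefficient at the carrier is taken, and the resulting displacement
#' phasor is converted to a velocity phasor (`x i 2 pi f0`, in m/s) and
#' assigned to the sub-FOV centre. The per-pixel field is obtained by
#' order-2 (quadratic) tensor interpolation between the centres, constant
#' beyond their hull.
#'
#' @param tracks A [link_tracks()] result.
#' @param schedule The [strobe_schedule()] of the acquisition.
#' @param f0 Carrier frequency (Hz).
#' @param image_size `c(rows, cols)` of the fast-camera frames.
#' @param pixel_pitch Fast-camera pixel pitch (um/px).
#' @param n Grid order; `NULL` (default) selects it by the five-particle
#'   rule.
#' @param min_per_cell Minimum complete tracks per sub-FOV.
#' @param phasor `"velocity"` (default) converts displacement phasors to
#'   velocity phasors; `"displacement"` keeps the literal displacement
#'   reading (m) for sensitivity checks.
#' @return An object of class `homodyne_flow_field`: complex matrices `u_x`,
#'   `u_y` (`image_size`), the sub-FOV node values, per-track phasors, and
#'   metadata.
#' @export
homodyne_flow <- function(tracks, schedule, f0, image_size, pixel_pitch,
                          n = NULL, min_per_cell = 5L,
                          phasor = c("velocity", "displacement")) {
  phasor <- match.arg(phasor)
  H <- image_size[1]; W <- image_size[2]
  ids <- complete_ids(tracks)
  nf <- attr(tracks, "n_frames")
  tt <- schedule$sample_times[seq_len(nf)]
  df <- tracks[tracks$id %in% ids, , drop = FALSE]
  if (!length(ids)) stop("no complete tracks: add more tracers")
  # per-track mean positions and per-frame displacements
  ord <- order(df$id, df$frame)
  df <- df[ord, ]
  mx <- tapply(df$x, df$id, mean)[as.character(ids)]
  my <- tapply(df$y, df$id, mean)[as.character(ids)]

  pick_n <- function(n) {
    cellx <- pmin(floor(mx / (W / n)), n - 1)
    celly <- pmin(floor(my / (H / n)), n - 1)
    tab <- table(factor(celly * n + cellx, levels = 0:(n^2 - 1)))
    all(tab >= min_per_cell)
  }
  if (is.null(n)) {
    n <- max(floor(sqrt(length(ids) / min_per_cell)), 1L)
    while (n > 1L && !pick_n(n)) n <- n - 1L
  }
  if (!pick_n(n))
    stop(sprintf(
      "no sub-FOV grid with >= %d complete tracks per cell; add more tracers",
      min_per_cell))

  scale <- pixel_pitch * 1e-6
  if (phasor == "velocity") scale <- scale * 2i * pi * f0

  # per-track homodyne phasors (used for residuals and the node averages)
  X <- matrix(df$x, nrow = nf)
  Y <- matrix(df$y, nrow = nf)
  X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
  ph_x <- homodyne_coefficient(X, tt, f0) * scale
  ph_y <- homodyne_coefficient(Y, tt, f0) * scale

  cellx <- pmin(floor(mx / (W / n)), n - 1)
  celly <- pmin(floor(my / (H / n)), n - 1)
  node_x <- (seq_len(n) - 0.5) * W / n
  node_y <- (seq_len(n) - 0.5) * H / n
  Vx <- matrix(0 + 0i, n, n); Vy <- matrix(0 + 0i, n, n)
  for (iy in 0:(n - 1)) for (ix in 0:(n - 1)) {
    sel <- which(cellx == ix & celly == iy)
    # sub-FOV average of displacements over particles, then homodyne:
    # equals the average of per-track homodyne phasors (linearity)
    Vx[iy + 1, ix + 1] <- mean(ph_x[sel])
    Vy[iy + 1, ix + 1] <- mean(ph_y[sel])
  }

  qx <- rep(0:(W - 1), each = H); qy <- rep(0:(H - 1), W)
  u_x <- matrix(quad_interp2(node_x, node_y, Vx, qx, qy), H, W)
  u_y <- matrix(quad_interp2(node_x, node_y, Vy, qx, qy), H, W)
  structure(
    list(u_x = u_x, u_y = u_y, n = n, node_x = node_x, node_y = node_y,
         node_values = list(x = Vx, y = Vy),
         track_phasors = data.frame(id = ids, x = as.numeric(mx),
                                    y = as.numeric(my)) |>
           within({u_x <- ph_x; u_y <- ph_y}),
         f0 = f0, pixel_pitch = pixel_pitch, phasor = phasor,
         image_size = as.integer(image_size)),
    class = "homodyne_flow_field")
}

#' @export
print.homodyne_flow_field <- function(x, ...) {
  cat(sprintf(
    "Homodyne flow field (%s phasor): %d x %d sub-FOV grid, |u| mean = %.3g\n",
    x$phasor, x$n, x$n, mean(Mod(x$u_x)) + mean(Mod(x$u_y))))
  invisible(x)
}

#' Wall shear-stress field from the homodyne flow field
#'
#' Applies the linear vertical-gradient approximation
#' `sigma_k = mu * u_k(z = R_b) / R_b` pixel-wise, where `u_k` is the
#' velocity phasor at the bead height.
#'
#' @param flow A [homodyne_flow()] result (velocity phasors).
#' @param mu Dynamic viscosity (Pa s).
#' @param R_b Bead radius (m).
#' @return An object of class `stress_field` with complex matrices
#'   `sigma_x`, `sigma_y` (Pa) and metadata.
#' @export
stress_field <- function(flow, mu = 1.0e-3, R_b = 1.5e-6) {
  stopifnot(inherits(flow, "homodyne_flow_field"), R_b > 0, mu > 0)
  structure(
    list(sigma_x = mu * flow$u_x / R_b, sigma_y = mu * flow$u_y / R_b,
         mu = mu, R_b = R_b, f0 = flow$f0, n = flow$n,
         pixel_pitch = flow$pixel_pitch,
         image_size = flow$image_size),
    class = "stress_field")
}

#' Self-consistency residual of the interpolated flow field
#'
#' Compares each complete track's own homodyne phasor against the
#' interpolated field at the track's mean position (the error estimate used
#' to budget the stress determination): the relative error is the root mean
#' squared residual over the root mean squared field value. Tracks whose
#' residual exceeds `outlier_factor` times the median are flagged.
#'
#' @param tracks A [link_tracks()] result.
#' @param flow The [homodyne_flow()] field built from them.
#' @param outlier_factor Flagging threshold on per-track residuals.
#' @return List with `relative_error`, per-track `residuals`, and
#'   `outliers` (ids).
#' @export
flow_residuals <- function(tracks, flow, outlier_factor = 5) {
  tp <- flow$track_phasors
  if (!nrow(tp)) stop("no complete tracks")
  fx <- bilinear_sample_cplx(flow$u_x, tp$y + 1, tp$x + 1)
  fy <- bilinear_sample_cplx(flow$u_y, tp$y + 1, tp$x + 1)
  res2 <- Mod(tp$u_x - fx)^2 + Mod(tp$u_y - fy)^2
  ref2 <- mean(Mod(fx)^2 + Mod(fy)^2)
  per_track <- sqrt(res2)
  med <- stats::median(per_track)
  out <- if (med > 0) tp$id[per_track > outlier_factor * med] else integer(0)
  list(relative_error = sqrt(mean(res2) / ref2),
       residuals = data.frame(id = tp$id, residual = per_track),
       outliers = out)
}
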