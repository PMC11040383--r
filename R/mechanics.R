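#' Homodyne pure and simple shear strain maps
#'
#' Differentiates the complex displacement phasor maps on the DIC-box grid
#' (central differences, one-sided at the borders) and forms the pure shear
#' `gamma_p = d(delta_x)/dx + d(delta_y)/dy` and simple shear
#' `gamma_s = d(delta_x)/dy + d(delta_y)/dx`. The four directional
#' derivative maps are kept alongside, since the modulus inversion pairs
#' each with its stress component. Note that the quantity called "pure
#' shear" here is, in standard continuum nomenclature, the planar
#' divergence; the printed formula is used as is.
#'
#' @param dmap A [homodyne_displacement()] result (displacements in um).
#' @param spacing Grid spacing between box centres (um); defaults to
#'   `box_size * pixel_pitch` from the map.
#' @return An object of class `strain_maps`: complex matrices `gamma_p`,
#'   `gamma_s` and the derivatives `ddx_dx`, `ddx_dy`, `ddy_dx`, `ddy_dy`
#'   (dimensionless). NA propagates from invalid boxes to their stencil.
#' @export
shear_strains <- function(dmap, spacing = NULL) {
  stopifnot(inherits(dmap, "homodyne_displacement_map"))
  if (is.null(spacing)) spacing <- dmap$box_size * dmap$pixel_pitch
  dx <- dmap$delta_x; dy <- dmap$delta_y
  ddx_dx <- grad_map(dx, spacing, "x")
  ddx_dy <- grad_map(dx, spacing, "y")
  ddy_dx <- grad_map(dy, spacing, "x")
  ddy_dy <- grad_map(dy, spacing, "y")
  structure(
    list(gamma_p = ddx_dx + ddy_dy, gamma_s = ddx_dy + ddy_dx,
         ddx_dx = ddx_dx, ddx_dy = ddx_dy, ddy_dx = ddy_dx, ddy_dy = ddy_dy,
         box_x = dmap$box_x, box_y = dmap$box_y, spacing = spacing,
         box_size = dmap$box_size, pixel_pitch = dmap$pixel_pitch,
         image_size = dmap$image_size),
    class = "strain_maps")
}

#' @export
print.strain_maps <- function(x, ...) {
  cat(sprintf("Strain maps: %d x %d boxes, median |gamma_p| = %.3g, |gamma_s| = %.3g\n",
              nrow(x$gamma_p), ncol(x$gamma_p),
              stats::median(Mod(x$gamma_p), na.rm = TRUE),
              stats::median(Mod(x$gamma_s), na.rm = TRUE)))
  invisible(x)
}

#' Sample a stress field at the DIC-box centres
#'
#' @param stress A [stress_field()] (per-pixel maps).
#' @param strains A [shear_strains()] result carrying the box grid.
#' @return List of complex matrices `sigma_x`, `sigma_y` on the box grid.
#' @export
stress_at_boxes <- function(stress, strains) {
  bx <- strains$box_x; by <- strains$box_y
  qr <- rep(by, times = length(bx)) + 1
  qc <- rep(bx, each = length(by)) + 1
  list(sigma_x = matrix(bilinear_sample_cplx(stress$sigma_x, qr, qc),
                        length(by), length(bx)),
       sigma_y = matrix(bilinear_sample_cplx(stress$sigma_y, qr, qc),
                        length(by), length(bx)))
}

#' Complex dynamic shear modulus maps
#'
#' Inverts the compliance relations per DIC-box:
#' `1/G_p = (1/sigma_x) d(delta_x)/dx + (1/sigma_y) d(delta_y)/dy` and
#' `1/G_s = (1/sigma_x) d(delta_x)/dy + (1/sigma_y) d(delta_y)/dx`, summing
#' only over stress components whose magnitude exceeds
#' `stress_threshold` times the larger of the two at that box (with one
#' component excluded the remaining term alone defines the compliance).
#' The combined modulus is `G = (G_p + G_s)/2` where both are defined,
#' degrading to the valid one otherwise. Under the `exp(+2i pi f0 t)`
#' phasor convention used throughout, strain lagging stress yields a
#' positive loss modulus `G'' = Im(G)`.
#'
#' @param strains A [shear_strains()] result.
#' @param stress Either a [stress_field()] (resampled onto the box grid) or
#'   a list with matrices/scalars `sigma_x`, `sigma_y` already on the grid.
#' @param stress_threshold Relative magnitude below which a stress
#'   component is excluded from the compliance sum.
#' @return An object of class `modulus_maps`: complex matrices `G_p`,
#'   `G_s`, `G` (Pa), real `G_storage`, `G_loss`, and `which_valid`
#'   (2 = both shears, 1 = pure only, -1 = simple only, 0 = undefined).
#' @export
shear_moduli <- function(strains, stress, stress_threshold = 0.1) {
  stopifnot(inherits(strains, "strain_maps"))
  nby <- nrow(strains$gamma_p); nbx <- ncol(strains$gamma_p)
  if (inherits(stress, "stress_field")) stress <- stress_at_boxes(stress, strains)
  as_grid <- function(s) {
    if (length(s) == 1L) matrix(s, nby, nbx) else s
  }
  sx <- as_grid(stress$sigma_x); sy <- as_grid(stress$sigma_y)
  mx <- Mod(sx); my <- Mod(sy)
  mmax <- pmax(mx, my)
  use_x <- mx >= stress_threshold * mmax & mx > 0
  use_y <- my >= stress_threshold * mmax & my > 0
  term <- function(use, s, d) {
    out <- matrix(0 + 0i, nby, nbx)
    out[use] <- d[use] / s[use]
    out[!use & is.na(d)] <- 0   # excluded direction: NA strain is harmless
    out[use & is.na(d)] <- NA_complex_
    out
  }
  none <- !use_x & !use_y
  inv_Gp <- term(use_x, sx, strains$ddx_dx) + term(use_y, sy, strains$ddy_dy)
  inv_Gs <- term(use_x, sx, strains$ddx_dy) + term(use_y, sy, strains$ddy_dx)
  inv_Gp[none] <- NA_complex_
  inv_Gs[none] <- NA_complex_
  G_p <- 1 / inv_Gp
  G_s <- 1 / inv_Gs
  G_p[Mod(inv_Gp) == 0] <- NA_complex_
  G_s[Mod(inv_Gs) == 0] <- NA_complex_
  ok_p <- !is.na(G_p); ok_s <- !is.na(G_s)
  G <- matrix(NA_complex_, nby, nbx)
  G[ok_p & ok_s] <- (G_p[ok_p & ok_s] + G_s[ok_p & ok_s]) / 2
  G[ok_p & !ok_s] <- G_p[ok_p & !ok_s]
  G[!ok_p & ok_s] <- G_s[!ok_p & ok_s]
  which_valid <- matrix(0L, nby, nbx)
  which_valid[ok_p & ok_s] <- 2L
  which_valid[ok_p & !ok_s] <- 1L
  which_valid[!ok_p & ok_s] <- -1L
  structure(
    list(G_p = G_p, G_s = G_s, G = G,
         G_storage = Re(G), G_loss = Im(G), which_valid = which_valid,
         box_x = strains$box_x, box_y = strains$box_y,
         box_size = strains$box_size, pixel_pitch = strains$pixel_pitch,
         image_size = strains$image_size),
    class = "modulus_maps")
}

#' @export
print.modulus_maps <- function(x, ...) {
  cat(sprintf(
    "Modulus maps: %d x %d boxes, median |G| = %.3g kPa (G' %.3g, G'' %.3g)\n",
    nrow(x$G), ncol(x$G), stats::median(Mod(x$G), na.rm = TRUE) / 1e3,
    stats::median(x$G_storage, na.rm = TRUE) / 1e3,
    stats::median(x$G_loss, na.rm = TRUE) / 1e3))
  invisible(x)
}

#' Map of the storage-to-loss modulus ratio
#'
#' Elementwise `log10(G'/G'')`; boxes where either component is
#' non-positive are masked (NA).
#'
#' @param m A [shear_moduli()] result.
#' @return Real matrix on the box grid.
#' @export
modulus_ratio_map <- function(m) {
  stopifnot(inherits(m, "modulus_maps"))
  out <- matrix(NA_real_, nrow(m$G), ncol(m$G))
  ok <- !is.na(m$G_storage) & !is.na(m$G_loss) &
    m$G_storage > 0 & m$G_loss > 0
  out[ok] <- log10(m$G_storage[ok] / m$G_loss[ok])
  out
}
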