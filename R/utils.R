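# Internal numeric helpers shared across modules.

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 1-D local quadratic Lagrange weights: value at xq from nodes xs (sorted,
# length >= 1) using the window of (up to) 3 nearest nodes. Returns the
# node indices and weights. Exact at the nodes; order-2 between them.
lagrange_window <- function(xs, xq) {
  m <- length(xs)
  if (m == 1L) return(list(idx = 1L, w = 1))
  xq <- min(max(xq, xs[1]), xs[m])   # clamp: constant extrapolation outside hull
  if (m == 2L) {
    w2 <- (xq - xs[1]) / (xs[2] - xs[1])
    return(list(idx = c(1L, 2L), w = c(1 - w2, w2)))
  }
  j <- which.min(abs(xs - xq))
  j <- min(max(j, 2L), m - 1L)
  id <- (j - 1L):(j + 1L)
  x0 <- xs[id[1]]; x1 <- xs[id[2]]; x2 <- xs[id[3]]
  w <- c((xq - x1) * (xq - x2) / ((x0 - x1) * (x0 - x2)),
         (xq - x0) * (xq - x2) / ((x1 - x0) * (x1 - x2)),
         (xq - x0) * (xq - x1) / ((x2 - x0) * (x2 - x1)))
  list(idx = id, w = w)
}

# Order-2 tensor-product interpolation of values V[iy, ix] given at node
# coordinates node_x (columns) and node_y (rows), evaluated at query points
# (qx, qy) (vectors of equal length). V may be complex. Passes exactly
# through the nodes; constant extrapolation outside the node hull.
quad_interp2 <- function(node_x, node_y, V, qx, qy) {
  stopifnot(length(node_y) == nrow(V), length(node_x) == ncol(V),
            length(qx) == length(qy))
  out <- vector(if (is.complex(V)) "complex" else "numeric", length(qx))
  for (i in seq_along(qx)) {
    lx <- lagrange_window(node_x, qx[i])
    ly <- lagrange_window(node_y, qy[i])
    out[i] <- sum(outer(ly$w, lx$w) * V[ly$idx, lx$idx, drop = FALSE])
  }
  out
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions
# (1-based). Out-of-range positions are clamped to the border. Vectorized.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- img[i00];          v10 <- img[i00 + 1]
  v01 <- img[i00 + nr];     v11 <- img[i00 + nr + 1]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

# Catmull-Rom cubic-convolution sampling of `img` at fractional (row, col)
# positions (1-based), clamped at the borders. Used by the renderer, where
# interpolation artifacts would otherwise masquerade as displacement noise.
bicubic_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(pmax(floor(row), 1), nr - 1L)
  c0 <- pmin(pmax(floor(col), 1), nc - 1L)
  fr <- row - r0; fc <- col - c0
  w <- function(f, k) {   # Catmull-Rom weights for taps k = -1, 0, 1, 2
    switch(k + 2L,
           ((-0.5 * f + 1) * f - 0.5) * f,
           (1.5 * f - 2.5) * f * f + 1,
           ((-1.5 * f + 2) * f + 0.5) * f,
           (0.5 * f - 0.5) * f * f)
  }
  out <- 0
  for (kr in -1:2) {
    rr <- pmin(pmax(r0 + kr, 1), nr)
    rowsum <- 0
    for (kc in -1:2) {
      cc <- pmin(pmax(c0 + kc, 1), nc)
      rowsum <- rowsum + w(fc, kc) * img[(cc - 1) * nr + rr]
    }
    out <- out + w(fr, kr) * rowsum
  }
  out
}

# Complex-aware bilinear resampling of a map onto query positions: real and
# imaginary parts are interpolated independently.
bilinear_sample_cplx <- function(img, row, col) {
  if (is.complex(img))
    complex(real = bilinear_sample(Re(img), row, col),
            imaginary = bilinear_sample(Im(img), row, col))
  else bilinear_sample(img, row, col)
}

# Central differences (one-sided at the borders) of a complex matrix along
# columns (x) or rows (y), with NA propagation. `h` is the grid spacing.
grad_map <- function(M, h, along = c("x", "y")) {
  along <- match.arg(along)
  if (along == "y") return(t(grad_map(t(M), h, "x")))
  nc <- ncol(M)
  if (nc < 2L) stop("need at least 2 grid points to differentiate")
  G <- M
  G[] <- NA_complex_
  if (nc > 2L)
    G[, 2:(nc - 1)] <- (M[, 3:nc] - M[, 1:(nc - 2)]) / (2 * h)
  G[, 1] <- (M[, 2] - M[, 1]) / h
  G[, nc] <- (M[, nc] - M[, nc - 1]) / h
  G
}
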