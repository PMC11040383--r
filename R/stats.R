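#' Tabulate valid DIC-boxes with labels and geometry
#'
#' Builds the statistical table of the analysis: one record per valid
#' DIC-box, carrying its position, modulus components, channel label and
#' distance to the cell edge. A box is labelled with a channel only if the
#' whole window spanning its own footprint plus `margin_boxes` neighbouring
#' boxes on each side lies inside that channel's (overlap-removed) mask, so
#' that the strain stencil never straddles the cell boundary; other boxes
#' are `"unassigned"` (NA label).
#'
#' @param moduli A [shear_moduli()] result.
#' @param masks A [remove_overlaps()] result (or named list of logical
#'   masks) on the fluorescence grid.
#' @param pixel_pitch um per pixel of the grid the masks live on.
#' @param affine Optional 2x3 transform mapping fluorescence to fast-camera
#'   coordinates; `NULL` means the grids coincide.
#' @param instance Optional integer matrix of cell instance labels (for
#'   cell-based statistics).
#' @param margin_boxes Neighbour margin (in boxes) required inside the mask.
#' @return data.frame of class `dic_box_table` with columns `x_um`, `y_um`,
#'   `channel`, `G_mod`, `G_storage`, `G_loss`, `edge_dist_um`, `cell`.
#' @export
dic_box_table <- function(moduli, masks, pixel_pitch = NULL, affine = NULL,
                          instance = NULL, margin_boxes = 1L) {
  stopifnot(inherits(moduli, "modulus_maps"))
  if (inherits(masks, "channel_masks")) masks <- masks$masks
  if (is.null(pixel_pitch)) pixel_pitch <- moduli$pixel_pitch
  nby <- nrow(moduli$G); nbx <- ncol(moduli$G)
  cx <- rep(moduli$box_x, each = nby)
  cy <- rep(moduli$box_y, times = nbx)
  # box centres in fluorescence coordinates
  if (is.null(affine)) { fx <- cx; fy <- cy } else {
    A <- affine[, 1:2]; b <- affine[, 3]
    inv <- solve(A)
    src <- inv %*% (rbind(cx, cy) - b)
    fx <- src[1, ]; fy <- src[2, ]
  }
  half_win <- (margin_boxes + 0.5) * moduli$box_size
  edge_maps <- lapply(masks, distance_to_edge, pixel_pitch = pixel_pitch)
  Hm <- nrow(masks[[1]]); Wm <- ncol(masks[[1]])

  window_inside <- function(mask, x, y) {
    r0 <- floor(y - half_win) + 1; r1 <- ceiling(y + half_win) + 1
    c0 <- floor(x - half_win) + 1; c1 <- ceiling(x + half_win) + 1
    if (r0 < 1 || c0 < 1 || r1 > Hm || c1 > Wm) return(FALSE)
    all(mask[r0:r1, c0:c1])
  }

  nb <- length(cx)
  channel <- rep(NA_character_, nb)
  edge <- rep(NA_real_, nb)
  cell <- rep(NA_integer_, nb)
  for (i in seq_len(nb)) {
    for (cn in names(masks)) {
      if (window_inside(masks[[cn]], fx[i], fy[i])) {
        channel[i] <- cn
        edge[i] <- edge_maps[[cn]][round(fy[i]) + 1, round(fx[i]) + 1]
        break
      }
    }
    if (!is.na(channel[i]) && !is.null(instance))
      cell[i] <- instance[round(fy[i]) + 1, round(fx[i]) + 1]
  }
  G <- as.vector(moduli$G)
  out <- data.frame(
    x_um = cx * pixel_pitch, y_um = cy * pixel_pitch,
    channel = channel,
    G_mod = Mod(G), G_storage = Re(G), G_loss = Im(G),
    edge_dist_um = edge, cell = cell)
  out <- out[!is.na(G), , drop = FALSE]
  class(out) <- c("dic_box_table", "data.frame")
  out
}

#' Population summaries and significance tests of DIC-box statistics
#'
#' Per-group summaries (median, mean, quartiles, SEM) of `|G|`, `G'` and
#' `G''`, Shapiro-Wilk normality per group, and pairwise two-sided
#' Mann-Whitney U tests between groups. Outliers (beyond 1.5 IQR) are
#' counted for plotting purposes but never excluded from the tests.
#'
#' @param table A [dic_box_table()] (rows with NA group are dropped).
#' @param group Column defining the groups (default `"channel"`).
#' @param values Measure columns to summarize and test.
#' @param holm Apply Holm correction across the pairwise comparisons.
#' @return An object of class `population_stats`: `summary` data.frame,
#'   `shapiro` data.frame, and `tests` (per measure, matrix of pairwise
#'   Mann-Whitney p-values), or `tests = NULL` for a single group.
#' @export
population_stats <- function(table, group = "channel",
                             values = c("G_mod", "G_storage", "G_loss"),
                             holm = FALSE) {
  tb <- table[!is.na(table[[group]]), , drop = FALSE]
  if (!nrow(tb)) stop("no labelled boxes to summarize")
  gs <- sort(unique(tb[[group]]))
  summ <- do.call(rbind, lapply(gs, function(g) {
    do.call(rbind, lapply(values, function(v) {
      x <- tb[[v]][tb[[group]] == g]
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      data.frame(group = g, measure = v, n = length(x),
                 median = stats::median(x), mean = mean(x),
                 q1 = q[1], q3 = q[2],
                 sem = stats::sd(x) / sqrt(length(x)),
                 n_outliers = sum(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr))
    }))
  }))
  shap <- do.call(rbind, lapply(gs, function(g) {
    do.call(rbind, lapply(values, function(v) {
      x <- tb[[v]][tb[[group]] == g]
      p <- if (length(x) >= 3) {
        if (length(x) > 5000) x <- with_seed(7L, sample(x, 5000))
        tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
      } else NA_real_
      data.frame(group = g, measure = v, shapiro_p = p)
    }))
  }))
  tests <- NULL
  if (length(gs) >= 2) {
    ns <- table(tb[[group]])
    if (min(ns) < 20)
      warning("fewer than 20 boxes in some group; tests may be underpowered")
    tests <- lapply(values, function(v) {
      m <- matrix(NA_real_, length(gs), length(gs),
                  dimnames = list(gs, gs))
      for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
        p <- suppressWarnings(stats::wilcox.test(
          tb[[v]][tb[[group]] == gs[i]], tb[[v]][tb[[group]] == gs[j]],
          alternative = "two.sided")$p.value)
        m[i, j] <- m[j, i] <- p
      }
      if (holm) {
        up <- upper.tri(m)
        m[up] <- stats::p.adjust(m[up], "holm")
        m[lower.tri(m)] <- t(m)[lower.tri(m)]
      }
      m
    })
    names(tests) <- values
  }
  structure(list(summary = summ, shapiro = shap, tests = tests,
                 group = group),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, digits = 3, ...) {
  cat("Population statistics (DIC-box based)\n")
  s <- x$summary
  s$median <- signif(s$median, digits); s$mean <- signif(s$mean, digits)
  s$sem <- signif(s$sem, digits)
  print(s[, c("group", "measure", "n", "median", "mean", "sem")],
        row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("Pairwise Mann-Whitney U (two-sided) p-values, |G|:\n")
    print(signif(x$tests[[1]], 3))
  }
  invisible(x)
}

#' Modulus profile versus distance to the cell edge
#'
#' @param table A [dic_box_table()].
#' @param bin_width Bin width in um.
#' @param group Grouping column.
#' @param value Measure column.
#' @return data.frame with `group`, `bin_center_um`, `mean`, `sem`, `n`
#'   (empty groups yield zero rows, not an error).
#' @export
edge_profile <- function(table, bin_width = 2, group = "channel",
                         value = "G_mod") {
  tb <- table[!is.na(table[[group]]) & !is.na(table$edge_dist_um), ,
              drop = FALSE]
  if (!nrow(tb))
    return(data.frame(group = character(0), bin_center_um = numeric(0),
                      mean = numeric(0), sem = numeric(0), n = integer(0)))
  out <- lapply(sort(unique(tb[[group]])), function(g) {
    x <- tb[tb[[group]] == g, , drop = FALSE]
    bins <- floor(x$edge_dist_um / bin_width)
    do.call(rbind, lapply(sort(unique(bins)), function(b) {
      v <- x[[value]][bins == b]
      data.frame(group = g, bin_center_um = (b + 0.5) * bin_width,
                 mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                 n = length(v))
    }))
  })
  do.call(rbind, out)
}

#' Loss-versus-storage pairs with local density
#'
#' Pairs `(G', G'')` of every positive box together with a Gaussian-kernel
#' density estimate over the plane (the customary density-coloured scatter
#' with the `G'' = G'` reference line).
#'
#' @param table A [dic_box_table()].
#' @param n_grid Density grid resolution per axis.
#' @return List with `pairs` (data.frame `G_storage`, `G_loss`, `density`)
#'   and the `kde` grid from [MASS::kde2d()] (NULL if fewer than 2 pairs).
#' @export
loss_vs_storage <- function(table, n_grid = 64) {
  sel <- !is.na(table$G_storage) & !is.na(table$G_loss) &
    table$G_storage > 0 & table$G_loss > 0
  x <- table$G_storage[sel]; y <- table$G_loss[sel]
  if (!length(x)) stop("no positive (G', G'') pairs")
  kde <- NULL
  dens <- rep(NA_real_, length(x))
  if (length(x) >= 2) {
    bw <- function(v) {
      h <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
      if (!is.finite(h) || h <= 0) h <- max(diff(range(v)) / 4, 1e-6 + 0.1 * max(abs(v)))
      h
    }
    kde <- MASS::kde2d(x, y, h = c(bw(x), bw(y)), n = n_grid)
    ix <- findInterval(x, kde$x, all.inside = TRUE)
    iy <- findInterval(y, kde$y, all.inside = TRUE)
    dens <- kde$z[cbind(ix, iy)]
  }
  list(pairs = data.frame(G_storage = x, G_loss = y, density = dens),
       kde = kde)
}

#' Strain noise floor from a blank region
#'
#' Measures the homodyne strain in an area without cells or tracers (where
#' the non-moving dish bottom is imaged) and reports it relative to the
#' typical strain over cell-labelled boxes: the analysis chain's relative
#' strain error.
#'
#' @param strains A [shear_strains()] result.
#' @param blank_mask Logical matrix (image grid): pixels with no cells and
#'   no tracers.
#' @param cell_mask Logical matrix (image grid): pixels inside cells.
#' @return List with `rel_strain_error`, `n_blank_boxes`, `n_cell_boxes`.
#' @export
blank_strain_noise <- function(strains, blank_mask, cell_mask) {
  stopifnot(inherits(strains, "strain_maps"))
  if (any(blank_mask & cell_mask))
    stop("blank mask overlaps the cell mask")
  amp <- sqrt(Mod(strains$gamma_p)^2 + Mod(strains$gamma_s)^2)
  half <- strains$box_size %/% 2
  box_all <- function(mask) {
    vapply(seq_along(amp), function(i) {
      iy <- (i - 1) %% nrow(amp) + 1; ix <- (i - 1) %/% nrow(amp) + 1
      y <- strains$box_y[iy]; x <- strains$box_x[ix]
      rows <- (y - half):(y + half) + 1; cols <- (x - half):(x + half) + 1
      all(mask[rows, cols])
    }, logical(1))
  }
  in_blank <- box_all(blank_mask) & !is.na(amp)
  in_cell <- box_all(cell_mask) & !is.na(amp)
  if (sum(in_blank) < 100)
    warning(sprintf("only %d blank boxes (>= 100 recommended)", sum(in_blank)))
  if (!sum(in_cell)) stop("no cell-labelled boxes with valid strains")
  list(rel_strain_error = stats::median(amp[in_blank]) /
         stats::median(amp[in_cell]),
       n_blank_boxes = sum(in_blank), n_cell_boxes = sum(in_cell))
}

#' Quadrature propagation of relative errors to the modulus
#'
#' The modulus is a ratio of stress and strain, so independent relative
#' errors combine in quadrature: `sqrt(a^2 + b^2)`.
#'
#' @param rel_flow_error Relative error of the flow/stress determination.
#' @param rel_strain_error Relative error of the strain determination.
#' @return Relative modulus error (fraction).
#' @export
propagate_errors <- function(rel_flow_error, rel_strain_error) {
  stopifnot(rel_flow_error >= 0, rel_strain_error >= 0)
  sqrt(rel_flow_error^2 + rel_strain_error^2)
}

#' Systematic stress-error bound from the depth of field
#'
#' Tracers are assumed to sit at `z = R_b`; any tracer within the depth of
#' field but off that height biases the velocity-gradient estimate by up to
#' `depth_of_field / R_b` relative.
#'
#' @param depth_of_field Depth of field (um, one-sided).
#' @param R_b Bead radius (um).
#' @return Relative systematic stress-error bound (fraction).
#' @export
depth_of_field_bias <- function(depth_of_field, R_b) {
  stopifnot(R_b > 0, depth_of_field >= 0)
  depth_of_field / R_b
}

#' Assemble the analysis error budget
#'
#' @param rel_flow_error From [flow_residuals()].
#' @param rel_strain_error From [blank_strain_noise()].
#' @param depth_of_field,R_b For the systematic bound (um).
#' @return An object of class `error_budget`.
#' @export
error_budget <- function(rel_flow_error, rel_strain_error,
                         depth_of_field = 0.87, R_b = 1.5) {
  structure(
    list(rel_flow_error = rel_flow_error,
         rel_strain_error = rel_strain_error,
         rel_modulus_error = propagate_errors(rel_flow_error,
                                              rel_strain_error),
         systematic_stress_error_bound =
           depth_of_field_bias(depth_of_field, R_b)),
    class = "error_budget")
}

#' @export
print.error_budget <- function(x, ...) {
  cat("Error budget (relative):\n")
  cat(sprintf("  flow / stress       : %.1f%%\n", 100 * x$rel_flow_error))
  cat(sprintf("  strain noise floor  : %.1f%%\n", 100 * x$rel_strain_error))
  cat(sprintf("  modulus (propagated): %.1f%%\n", 100 * x$rel_modulus_error))
  cat(sprintf("  systematic stress bound (depth of field): %.0f%%\n",
              100 * x$systematic_stress_error_bound))
  invisible(x)
}

#' Compare DIC-box based and cell-based statistics
#'
#' Aggregates the box table per cell (cell means) and compares, per group,
#' the DIC-box based distribution (DS) with the cell-based distribution
#' (CS): group means with their SEMs and a two-sided Mann-Whitney test of
#' the two distributions.
#'
#' @param table A [dic_box_table()] with the `cell` column populated.
#' @param value Measure column.
#' @param group Grouping column.
#' @return data.frame, one row per group, with DS/CS means, SEMs, cell and
#'   box counts, and the Mann-Whitney p-value.
#' @export
compare_box_cell_stats <- function(table, value = "G_mod",
                                   group = "channel") {
  tb <- table[!is.na(table[[group]]) & !is.na(table$cell), , drop = FALSE]
  if (!nrow(tb)) stop("no boxes with cell instance labels")
  do.call(rbind, lapply(sort(unique(tb[[group]])), function(g) {
    x <- tb[tb[[group]] == g, , drop = FALSE]
    ds <- x[[value]]
    cs <- as.numeric(tapply(ds, x$cell, mean))
    p <- suppressWarnings(stats::wilcox.test(ds, cs)$p.value)
    data.frame(group = g,
               mean_ds = mean(ds), sem_ds = stats::sd(ds) / sqrt(length(ds)),
               mean_cs = mean(cs), sem_cs = stats::sd(cs) / sqrt(length(cs)),
               n_boxes = length(ds), n_cells = length(cs),
               mw_p = p)
  }))
}
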