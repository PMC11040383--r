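#' Default analysis configuration
#'
#' @param box_size DIC comparison box side (px).
#' @param search_radius DIC search radius (px).
#' @param min_contrast Minimum DIC patch contrast.
#' @param stress_threshold Relative stress-component threshold of the
#'   compliance sum.
#' @param subfov_n Sub-FOV grid order for the flow field (`NULL` = select
#'   by the five-particle rule).
#' @param min_per_cell Minimum complete tracks per sub-FOV.
#' @param mu Dynamic viscosity (Pa s); `NULL` = take from the scene.
#' @param R_b_um Bead radius (um); `NULL` = take from the scene.
#' @param affine Optional 2x3 fluorescence-to-fast-camera transform.
#' @param blur_sigma_frac Segmentation background-blur fraction.
#' @param depth_of_field_um One-sided depth of field for the systematic
#'   stress bound (um).
#' @param bin_width_um Edge-profile bin width (um).
#' @return Named list of analysis parameters.
#' @export
mechanotype_config <- function(box_size = 5L, search_radius = 10L,
                               min_contrast = 0.01, stress_threshold = 0.1,
                               subfov_n = NULL, min_per_cell = 5L,
                               mu = NULL, R_b_um = NULL, affine = NULL,
                               blur_sigma_frac = 1 / 8,
                               depth_of_field_um = 0.87,
                               bin_width_um = 2) {
  list(box_size = box_size, search_radius = search_radius,
       min_contrast = min_contrast, stress_threshold = stress_threshold,
       subfov_n = subfov_n, min_per_cell = min_per_cell, mu = mu,
       R_b_um = R_b_um, affine = affine, blur_sigma_frac = blur_sigma_frac,
       depth_of_field_um = depth_of_field_um, bin_width_um = bin_width_um)
}

#' Run the full mechanotyping analysis
#'
#' Executes the analysis chain on a (synthetic or loaded) experiment:
#' fluorescence segmentation, bead tracking and homodyne flow/stress
#' estimation, digital image correlation and homodyne displacement maps,
#' strain and modulus maps, DIC-box statistics and the error budget.
#' Optional stages degrade gracefully (e.g. without fluorescence the
#' population statistics are skipped); mandatory failures abort with the
#' failing stage recorded.
#'
#' @param sim A `strobomech_sim` from [simulate_experiment()] (or a dataset
#'   directory written by [write_scene_dataset()]).
#' @param config Analysis parameters from [mechanotype_config()].
#' @param verbose Print stage progress.
#' @return An object of class `mechanotype_run` with the stage report, all
#'   intermediate fields and the statistics.
#' @export
run_pipeline <- function(sim, config = mechanotype_config(),
                         verbose = FALSE) {
  if (is.character(sim)) sim <- read_scene_dataset(sim)
  stopifnot(inherits(sim, "strobomech_sim"))
  scene <- sim$scene
  cfg <- utils::modifyList(mechanotype_config(), config[!vapply(config, is.null, logical(1))])
  if (is.null(cfg$mu)) cfg$mu <- scene$mu
  if (is.null(cfg$R_b_um)) cfg$R_b_um <- scene$bead_radius_um
  stages <- list()
  res <- list(scene = scene, config = cfg, schedule = sim$schedule)
  tic <- function() proc.time()[["elapsed"]]
  note <- function(name, status, t0) {
    stages[[name]] <<- list(status = status,
                            seconds = round(tic() - t0, 2))
    if (verbose) message(sprintf("[%s] %s (%.1fs)", name, status, tic() - t0))
  }

  # --- segmentation (optional) ------------------------------------------
  t0 <- tic()
  if (!is.null(sim$fluorescence) && length(sim$fluorescence)) {
    raw_masks <- lapply(sim$fluorescence, segment_channel,
                        blur_sigma_frac = cfg$blur_sigma_frac)
    res$masks <- if (length(raw_masks) >= 2) remove_overlaps(raw_masks)
                 else structure(list(masks = raw_masks,
                                     overlap_removed = raw_masks[[1]] & FALSE,
                                     overlap_fraction = 0),
                                class = "channel_masks")
    note("segmentation", "ok", t0)
  } else note("segmentation", "skipped (no fluorescence)", t0)

  # --- bead tracking and stress -----------------------------------------
  t0 <- tic()
  r_px <- cfg$R_b_um / scene$pixel_pitch
  F <- dim(sim$beads)[3]
  cents <- lapply(seq_len(F), function(f)
    detect_beads(sim$beads[, , f], radius_px = r_px))
  tracks <- link_tracks(cents)
  res$tracks <- tracks
  res$flow <- homodyne_flow(tracks, sim$schedule, sim$config$f0,
                            scene$image_size, scene$pixel_pitch,
                            n = cfg$subfov_n,
                            min_per_cell = cfg$min_per_cell)
  res$stress <- stress_field(res$flow, mu = cfg$mu,
                             R_b = cfg$R_b_um * 1e-6)
  res$flow_error <- flow_residuals(tracks, res$flow)
  note("tracking", "ok", t0)

  # --- DIC and homodyne displacement maps --------------------------------
  t0 <- tic()
  ref <- reference_image(sim$cells, sim$schedule)
  dstack <- dic_displacements(sim$cells, ref, box_size = cfg$box_size,
                              search_radius = cfg$search_radius,
                              min_contrast = cfg$min_contrast)
  if (!any(dstack$valid)) stop("no valid DIC boxes: image lacks texture")
  res$dmap <- homodyne_displacement(dstack, sim$schedule, sim$config$f0,
                                    pixel_pitch = scene$pixel_pitch)
  note("dic", "ok", t0)

  # --- strains and moduli ------------------------------------------------
  t0 <- tic()
  res$strains <- shear_strains(res$dmap)
  res$moduli <- shear_moduli(res$strains, res$stress,
                             stress_threshold = cfg$stress_threshold)
  res$ratio_map <- modulus_ratio_map(res$moduli)
  note("mechanics", "ok", t0)

  # --- statistics (needs masks) ------------------------------------------
  t0 <- tic()
  if (!is.null(res$masks)) {
    instance <- if (!is.null(sim$truth)) sim$truth$instance else NULL
    res$table <- dic_box_table(res$moduli, res$masks,
                               pixel_pitch = scene$pixel_pitch,
                               affine = cfg$affine, instance = instance)
    labelled <- res$table[!is.na(res$table$channel), , drop = FALSE]
    if (nrow(labelled)) {
      res$stats <- population_stats(res$table)
      res$edge_profile <- edge_profile(res$table,
                                       bin_width = cfg$bin_width_um)
      res$loss_vs_storage <- loss_vs_storage(labelled)
      note("statistics", "ok", t0)
    } else note("statistics", "skipped (no labelled boxes)", t0)
  } else note("statistics", "skipped (no masks)", t0)

  # --- validation / error budget -----------------------------------------
  t0 <- tic()
  blank <- tryCatch({
    cell_mask <- if (!is.null(res$masks))
      Reduce(`|`, res$masks$masks) else matrix(FALSE, scene$image_size[1],
                                               scene$image_size[2])
    brush <- function(k) EBImage::makeBrush(2L * as.integer(k) + 1L, "disc")
    cellsD <- EBImage::dilate(cell_mask * 1, brush(2 * cfg$box_size)) > 0
    beadD <- matrix(FALSE, scene$image_size[1], scene$image_size[2])
    b1 <- cents[[1]]
    amp_px <- max(Mod(scene$flow_u)) / (2 * pi * sim$config$f0) /
      (scene$pixel_pitch * 1e-6)
    for (k in seq_len(nrow(b1)))
      beadD <- draw_disc(beadD * 1, b1$x[k], b1$y[k],
                         r_px + amp_px + 3, -1) > 0
    blank_mask <- !cellsD & !beadD
    suppressWarnings(blank_strain_noise(res$strains, blank_mask, cell_mask))
  }, error = function(e) NULL)
  if (!is.null(blank)) {
    res$blank <- blank
    res$budget <- error_budget(res$flow_error$relative_error,
                               blank$rel_strain_error,
                               depth_of_field = cfg$depth_of_field_um,
                               R_b = cfg$R_b_um)
    note("validation", "ok", t0)
  } else note("validation", "skipped (no blank region)", t0)

  res$report <- list(stages = stages, seed = scene$seed,
                     f0 = sim$config$f0, n_pulses = sim$config$n_pulses,
                     n_frames = sim$config$n_frames)
  class(res) <- "mechanotype_run"
  res
}

#' @export
print.mechanotype_run <- function(x, ...) {
  cat("Stroboscopic mechanotyping run\n")
  for (s in names(x$report$stages))
    cat(sprintf("  %-12s %s (%.1fs)\n", s, x$report$stages[[s]]$status,
                x$report$stages[[s]]$seconds))
  if (!is.null(x$stats)) {
    s <- x$stats$summary
    s <- s[s$measure == "G_mod", ]
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-8s median |G| = %.2f kPa (mean %.2f, n = %d boxes)\n",
                  s$group[i], s$median[i] / 1e3, s$mean[i] / 1e3, s$n[i]))
    if (!is.null(x$stats$tests)) {
      p <- x$stats$tests$G_mod
      cat(sprintf("  Mann-Whitney |G| p = %.3g\n", min(p, na.rm = TRUE)))
    }
  }
  if (!is.null(x$budget)) print(x$budget)
  invisible(x)
}

#' @export
summary.mechanotype_run <- function(object, ...) {
  if (is.null(object$stats)) {
    cat("No population statistics (no masks).\n")
    return(invisible(NULL))
  }
  object$stats$summary
}

#' @export
plot.mechanotype_run <- function(x, which = c("modulus", "ratio", "boxplot"),
                                 ...) {
  which <- match.arg(which)
  if (which == "modulus") {
    m <- Mod(x$moduli$G) / 1e3
    graphics::image(t(m)[, rev(seq_len(nrow(m)))],
                    col = grDevices::hcl.colors(64, "viridis"),
                    main = "|G| (kPa)", axes = FALSE, ...)
  } else if (which == "ratio") {
    graphics::image(t(x$ratio_map)[, rev(seq_len(nrow(x$ratio_map)))],
                    col = grDevices::hcl.colors(64, "RdBu"),
                    main = "log10(G'/G'')", axes = FALSE, ...)
  } else {
    tb <- x$table[!is.na(x$table$channel), ]
    graphics::boxplot(G_mod / 1e3 ~ channel, data = tb, outline = FALSE,
                      ylab = "|G| (kPa)", ...)
  }
  invisible(x)
}
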