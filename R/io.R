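#' Write a synthetic dataset to disk
#'
#' Emits the multi-page grayscale TIFF stacks (fast-camera cells and beads,
#' per-channel fluorescence), the ground-truth modulus map (real and
#' imaginary floating-point TIFFs), the ground-truth bead tracks as CSV and
#' a YAML manifest from which [read_scene_dataset()] can rebuild the
#' experiment for [run_pipeline()].
#'
#' @param sim A `strobomech_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "strobomech_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clamp <- function(a) pmin(pmax(a, 0), 1)
  stack_list <- function(a) lapply(seq_len(dim(a)[3]), function(k) clamp(a[, , k]))
  tiff::writeTIFF(stack_list(sim$cells), file.path(dir, "cells.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(stack_list(sim$beads), file.path(dir, "beads.tif"),
                  bits.per.sample = 16L)
  for (cn in names(sim$fluorescence))
    tiff::writeTIFF(stack_list(sim$fluorescence[[cn]]),
                    file.path(dir, sprintf("fluo_%s.tif", cn)),
                    bits.per.sample = 16L)
  G <- sim$truth$G_map
  G[is.na(G)] <- 0
  tiff::writeTIFF(Re(G) / 1e6, file.path(dir, "truth_G_real.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(Im(G) / 1e6, file.path(dir, "truth_G_imag.tif"),
                  bits.per.sample = 32L)
  utils::write.csv(sim$truth_tracks, file.path(dir, "truth_tracks.csv"),
                   row.names = FALSE)
  scene <- sim$scene
  manifest <- list(
    image_size = scene$image_size, pixel_pitch = scene$pixel_pitch,
    bead_radius_um = scene$bead_radius_um, mu = scene$mu,
    noise_sigma = scene$noise_sigma, seed = scene$seed,
    flow_u = list(x = c(Re(scene$flow_u[1]), Im(scene$flow_u[1])),
                  y = c(Re(scene$flow_u[2]), Im(scene$flow_u[2]))),
    acquisition = list(f0_hz = sim$config$f0, alpha_hz = sim$config$alpha,
                       n_pulses = sim$config$n_pulses,
                       f_repet_hz = sim$config$f_repet,
                       n_frames = sim$config$n_frames),
    channels = names(sim$fluorescence))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset directory back into an experiment object
#'
#' @param dir Directory written by [write_scene_dataset()] (images plus
#'   `manifest.yaml`).
#' @return A `strobomech_sim` suitable for [run_pipeline()] (without the
#'   in-memory ground truth beyond what is stored on disk).
#' @export
read_scene_dataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  read_stack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
  cells <- read_stack(file.path(dir, "cells.tif"))
  beads <- read_stack(file.path(dir, "beads.tif"))
  fluo <- lapply(man$channels, function(cn)
    read_stack(file.path(dir, sprintf("fluo_%s.tif", cn))))
  names(fluo) <- man$channels
  config <- pulse_train_config(
    f0 = man$acquisition$f0_hz, alpha = man$acquisition$alpha_hz,
    n_pulses = man$acquisition$n_pulses,
    f_repet = man$acquisition$f_repet_hz,
    n_frames = man$acquisition$n_frames)
  scene <- scene_spec(
    image_size = unlist(man$image_size), pixel_pitch = man$pixel_pitch,
    cells = list(), n_beads = 0L,
    bead_xy = data.frame(x = numeric(0), y = numeric(0)),
    bead_radius_um = man$bead_radius_um,
    flow_u = c(x = complex(real = man$flow_u$x[1],
                           imaginary = man$flow_u$x[2]),
               y = complex(real = man$flow_u$y[1],
                           imaginary = man$flow_u$y[2])),
    mu = man$mu, noise_sigma = man$noise_sigma, seed = man$seed)
  truth <- NULL
  gr <- file.path(dir, "truth_G_real.tif")
  if (file.exists(gr)) {
    G <- complex(real = tiff::readTIFF(gr),
                 imaginary = tiff::readTIFF(file.path(dir, "truth_G_imag.tif"))) * 1e6
    G <- matrix(G, dim(cells)[1], dim(cells)[2])
    G[Mod(G) == 0] <- NA_complex_
    truth <- list(G_map = G, instance = NULL)
  }
  structure(
    list(scene = scene, config = config, schedule = strobe_schedule(config),
         cells = cells, beads = beads, fluorescence = fluo,
         truth = truth,
         truth_tracks = tryCatch(
           utils::read.csv(file.path(dir, "truth_tracks.csv")),
           error = function(e) NULL)),
    class = "strobomech_sim")
}

#' Write the outputs of a run to disk
#'
#' Emits the DIC-box table (CSV), the amplitude/phase and modulus maps
#' (floating-point TIFFs, moduli in MPa so values stay in range) and a JSON
#' report with stage status, statistics and the error budget.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "mechanotype_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_map <- function(m, name) {
    m[is.na(m)] <- 0
    tiff::writeTIFF(pmin(pmax(m, 0), 1), file.path(dir, name),
                    bits.per.sample = 32L)
    files <<- c(files, name)
  }
  amp <- sqrt(Mod(run$dmap$delta_x)^2 + Mod(run$dmap$delta_y)^2)
  put_map(amp / max(amp, na.rm = TRUE), "homodyne_amplitude.tif")
  put_map(Mod(run$moduli$G) / 1e6, "G_mod_MPa.tif")
  put_map((run$ratio_map + 3) / 6, "log10_ratio_scaled.tif")
  if (!is.null(run$table)) {
    utils::write.csv(run$table, file.path(dir, "boxes.csv"),
                     row.names = FALSE)
    files <- c(files, "boxes.csv")
  }
  report <- list(
    schema = "mechanotype_run/1",
    seed = run$report$seed,
    stages = run$report$stages,
    error_budget = if (!is.null(run$budget)) unclass(run$budget),
    statistics = if (!is.null(run$stats)) list(
      summary = run$stats$summary,
      shapiro = run$stats$shapiro,
      mann_whitney_G = run$stats$tests$G_mod),
    files = files)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
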