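test_that("analytic inversion of the generated field recovers G_true", {
  set.seed(4)
  G <- stats::runif(20, 1e3, 10e3) * exp(1i * stats::runif(20, 0.1, 1.2))
  sc <- grid_scene(G, size = 400L)
  dmap <- truth_displacement_map(sc)
  st <- shear_strains(dmap)
  sig <- scene_stress_true(sc)
  mod <- shear_moduli(st, list(sigma_x = sig[["x"]], sigma_y = sig[["y"]]))
  Gt <- ground_truth_displacement(sc)$G_map[dmap$box_y + 1, dmap$box_x + 1]
  sel <- interior_boxes(sc, dmap) & !is.na(mod$G) & !is.na(Gt)
  expect_gt(sum(sel), 20 * 10)
  rel <- Mod(mod$G[sel] - Gt[sel]) / Mod(Gt[sel])
  expect_lt(max(rel), 1e-6)
})

test_that("a purely viscous cell produces quadrature displacement gradients", {
  sc <- grid_scene(5000i, size = 96L,
                   flow_u = c(x = 1 + 0i, y = 0.5 + 0i))
  dmap <- truth_displacement_map(sc)
  st <- shear_strains(dmap)
  sig <- scene_stress_true(sc)
  sel <- interior_boxes(sc, dmap) & Mod(st$ddx_dx) > 0
  # gradient carries phase -pi/2 relative to the (real) stress phasor
  ph <- Arg(st$ddx_dx[sel] / sig[["x"]])
  expect_equal(max(abs(ph + pi / 2)), 0, tolerance = 1e-9)
})

test_that("zero stress with cells present is rejected", {
  sc <- grid_scene(5000 + 0i, size = 96L, flow_u = c(x = 0i, y = 0i))
  expect_error(ground_truth_displacement(sc), "zero stress")
})

test_that("null motion renders identical frames; fixed seeds render identically", {
  sc <- scene_spec(image_size = c(64L, 64L), cells = list(), n_beads = 3L,
                   flow_u = c(x = 0i, y = 0i), noise_sigma = 0, seed = 5L)
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 10L)
  sch <- strobe_schedule(cfg)
  stk <- render_strobe_stack(sc, sch, cfg)
  for (n in 2:dim(stk$cells)[3]) {
    expect_identical(stk$cells[, , n], stk$cells[, , 1])
    expect_identical(stk$beads[, , n], stk$beads[, , 1])
  }
  # determinism under a fixed seed, byte for byte
  sc2 <- two_population_scene(image_size = c(64L, 64L), n_per_pop = 1L,
                              seed = 12L)
  cfg2 <- pulse_train_config(30e3, 10e3, n_pulses = 12L)
  a <- render_strobe_stack(sc2, strobe_schedule(cfg2), cfg2)
  b <- render_strobe_stack(sc2, strobe_schedule(cfg2), cfg2)
  expect_identical(a$cells, b$cells)
  expect_identical(a$beads, b$beads)
})

test_that("bead oscillation amplitude equals v / (2 pi f0)", {
  sc <- scene_spec(image_size = c(64L, 64L), cells = list(), n_beads = 1L,
                   bead_xy = data.frame(x = 32, y = 32),
                   flow_u = c(x = 1 + 0i, y = 0i), noise_sigma = 0, seed = 2L)
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 200L)
  sch <- strobe_schedule(cfg)
  stk <- render_strobe_stack(sc, sch, cfg)
  tr <- stk$truth_tracks
  x <- tr$x_px[order(tr$frame)]
  coefs <- homodyne_coefficient(x - mean(x), sch$sample_times, 30e3)
  amp_um <- Mod(coefs) / mean(stk$envelope) * sc$pixel_pitch
  expect_equal(amp_um, 1 / (2 * pi * 30e3) * 1e6, tolerance = 0.02)
})

test_that("oversized displacements are refused", {
  sc <- scene_spec(image_size = c(64L, 64L), cells = list(), n_beads = 1L,
                   flow_u = c(x = 40 + 0i, y = 0i), seed = 2L)
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 10L)
  expect_error(render_strobe_stack(sc, strobe_schedule(cfg), cfg),
               "half the image")
})

test_that("fluorescence rendering exposes masks, overlaps and backgrounds", {
  cells <- list(cell_spec(c(30, 30), c(12, 10), channel = "green"),
                cell_spec(c(38, 30), c(10, 9), channel = "orange"))
  sc <- scene_spec(image_size = c(64L, 64L), cells = cells, n_beads = 1L,
                   seed = 3L)
  fl <- render_fluorescence(sc, n_images = 3L, background_amplitude = 0,
                            noise_sd = 0)
  masks <- scene_masks(sc)$channel
  # noise- and background-free: a plain threshold recovers the mask exactly
  expect_identical(fl$green[, , 1] > 0.4, masks$green)
  # overlap pixels bright in both channels
  ov <- masks$green & masks$orange
  expect_gt(sum(ov), 0)
  expect_true(all(fl$orange[, , 1][ov] > 0.4))
  expect_true(all(fl$green[, , 1][ov] > 0.4))
})
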