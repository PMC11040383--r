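test_that("reference image averages exactly the rest frames", {
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 1000L)
  sch <- strobe_schedule(cfg)     # N_aq = 3N/2 = 1500
  expect_equal(sch$n_frames, 1500L)
  stack <- array(0, c(2, 2, 1500))
  stack[1, 1, ] <- seq_len(1500)  # rest frames are 1001..1500
  ref <- reference_image(stack, sch)
  expect_equal(ref[1, 1], mean(1001:1500))
  # averaging K noisy rest frames shrinks the noise ~ 1/sqrt(K)
  set.seed(3)
  cfg2 <- pulse_train_config(30e3, 10e3, n_pulses = 100L, n_frames = 600L)
  sch2 <- strobe_schedule(cfg2)
  stk2 <- array(stats::rnorm(16 * 16 * 600, mean = 0.5, sd = 0.1),
                c(16, 16, 600))
  ref2 <- reference_image(stk2, sch2)
  expect_lt(stats::sd(ref2 - 0.5), 0.1 / sqrt(500) * 1.3)
  # no rest frames -> error
  cfg3 <- pulse_train_config(30e3, 10e3, n_pulses = 10L, n_frames = 10L)
  expect_error(reference_image(array(0, c(2, 2, 10)), strobe_schedule(cfg3)),
               "rest frames")
})

test_that("DIC is exact on integer shifts and flags textureless boxes", {
  tex <- speckle_image(96L)
  frame <- tex
  frame[3:96, 2:96] <- tex[1:94, 1:95]   # content moved +1 col (x), +2 rows (y)
  d <- dic_displacements(frame, tex, box_size = 5L, search_radius = 4L)
  sel <- d$valid
  sel[c(1, nrow(sel)), ] <- FALSE; sel[, c(1, ncol(sel))] <- FALSE
  expect_true(all(abs(d$delta_x[, , 1][sel] - 1) < 1e-9))
  expect_true(all(abs(d$delta_y[, , 1][sel] - 2) < 1e-9))
  # identity: zero field
  d0 <- dic_displacements(tex, tex, box_size = 5L, search_radius = 4L)
  expect_lt(max(abs(d0$delta_x[, , 1][d0$valid])), 1e-9)
  # textureless reference: everything invalid
  flat <- matrix(0.5, 96, 96)
  df <- dic_displacements(flat, flat, box_size = 5L, search_radius = 4L)
  expect_false(any(df$valid))
})

test_that("sub-pixel shifts are recovered within 0.05 px", {
  tex <- speckle_image(96L)
  fr <- fourier_shift(tex, 0.3, 0)
  d <- dic_displacements(fr, tex, box_size = 5L, search_radius = 4L)
  expect_lt(abs(mean(d$delta_x[, , 1][d$valid]) - 0.3), 0.05)
  expect_lt(abs(mean(d$delta_y[, , 1][d$valid])), 0.05)
})

test_that("homodyne displacement maps extract tone amplitude and phase", {
  cfg <- pulse_train_config(30e3, 10e3, n_pulses = 120L)
  sch <- strobe_schedule(cfg)
  ds <- tone_displacement_stack(0.8, 0.3, sch, 30e3)
  hm <- homodyne_displacement(ds, sch, 30e3, pixel_pitch = 0.514)
  expect_equal(Mod(hm$delta_x[2, 3]), 0.8 * 0.514, tolerance = 1e-9)
  expect_equal(Arg(hm$delta_x[2, 3]), -pi / 2, tolerance = 1e-9)
  expect_equal(Mod(hm$delta_y[1, 1]), 0.3 * 0.514, tolerance = 1e-9)
  # static stack -> zero map
  ds0 <- tone_displacement_stack(0, 0, sch, 30e3)
  hm0 <- homodyne_displacement(ds0, sch, 30e3)
  expect_lt(max(Mod(hm0$delta_x)), 1e-12)
  # a static offset common to all frames is rejected by the projection
  dso <- tone_displacement_stack(0.8, 0.3, sch, 30e3, offset = 2.7)
  hmo <- homodyne_displacement(dso, sch, 30e3, pixel_pitch = 0.514)
  expect_equal(hmo$delta_x, hm$delta_x, tolerance = 1e-9)
  # invalid boxes propagate as NA
  dsb <- tone_displacement_stack(0.8, 0.3, sch, 30e3)
  dsb$valid[1, 1] <- FALSE
  expect_true(is.na(homodyne_displacement(dsb, sch, 30e3)$delta_x[1, 1]))
})

test_that("warp to fluorescence respects identity, translation and scaling", {
  xg <- outer(seq(0, 1, length.out = 60), seq(0, 1, length.out = 60), "+")
  blob <- exp(-((row(xg) - 25)^2 + (col(xg) - 35)^2) / 60) *
    exp(1i * 0.4) + 0.2 * xg
  idw <- warp_to_fluorescence(blob, diag(1, 2, 3))
  expect_equal(idw, blob, tolerance = 1e-12)
  # translation by (10, 0) px in the affine moves features by exactly -10
  tr <- matrix(c(1, 0, 0, 1, 10, 0), 2, 3)
  w <- warp_to_fluorescence(blob, tr)
  expect_equal(w[30, 20], blob[30, 30], tolerance = 1e-12)
  # pure 2x scaling preserves amplitudes at corresponding points
  scl <- matrix(c(2, 0, 0, 2, 0, 0), 2, 3)
  ws <- warp_to_fluorescence(blob, scl)
  expect_equal(Mod(ws[13, 16]), Mod(blob[25, 31]), tolerance = 0.02)
  expect_error(warp_to_fluorescence(blob, matrix(0, 2, 3)), "singular")
})
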