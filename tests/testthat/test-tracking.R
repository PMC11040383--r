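test_that("bead detection finds sub-pixel centroids and suppresses duplicates", {
  img <- matrix(0.6, 80, 80)
  pos <- data.frame(x = c(20.3, 50.7, 33.2), y = c(25.6, 60.1, 70.4))
  for (i in 1:3)
    img <- strobomech:::draw_disc(img, pos$x[i], pos$y[i], 3, 0.4)
  det <- detect_beads(img, radius_px = 3)
  expect_equal(nrow(det), 3)
  ord <- order(det$x)
  pord <- order(pos$x)
  expect_lt(max(abs(det$x[ord] - pos$x[pord])), 0.1)
  expect_lt(max(abs(det$y[ord] - pos$y[pord])), 0.1)
  # blank frame
  expect_equal(nrow(detect_beads(matrix(0.6, 40, 40))), 0)
  # two beads 1 px apart are merged, never over-counted
  img2 <- matrix(0.6, 40, 40)
  img2 <- strobomech:::draw_disc(img2, 20, 20, 3, 0.4)
  img2 <- strobomech:::draw_disc(img2, 21, 20, 3, 0.4)
  expect_lte(nrow(detect_beads(img2, radius_px = 3)), 2)
})

test_that("nearest-neighbour linking keeps identities and flags losses", {
  cfg <- pulse_train_config(30e3, 10e3, n_pulses = 40L)
  sch <- strobe_schedule(cfg)
  base <- expand.grid(x = c(20, 60, 100), y = c(20, 60, 100))
  cents <- oscillating_centroids(base, amp_px = 2, sch, 30e3)
  tr <- link_tracks(cents)
  expect_length(complete_ids(tr), 9)
  # identity stability: track 1 stays at its base position on average
  t1 <- tr[tr$id == 1, ]
  expect_equal(mean(t1$x), base$x[1], tolerance = 0.1)
  # single frame: every centroid a length-1 track
  tr1 <- link_tracks(cents[1])
  expect_equal(nrow(tr1), 9)
  expect_length(complete_ids(tr1), 9)
  # a particle that disappears mid-sequence is incomplete
  cents2 <- cents
  for (f in 20:40) cents2[[f]] <- cents2[[f]][-1, ]
  tr2 <- link_tracks(cents2)
  expect_false(1 %in% complete_ids(tr2))
  expect_length(complete_ids(tr2), 8)
})

test_that("uniform bead oscillation yields a uniform velocity phasor field", {
  cfg <- pulse_train_config(30e3, 10e3, n_pulses = 120L)
  sch <- strobe_schedule(cfg)
  base <- expand.grid(x = c(15, 45, 75, 105), y = c(15, 45, 75, 105))
  A <- 1.5   # px
  cents <- oscillating_centroids(base, amp_px = A, sch, 30e3)
  tr <- link_tracks(cents)
  pitch <- 0.514
  fl <- homodyne_flow(tr, sch, 30e3, c(120L, 120L), pitch)
  expected <- A * pitch * 1e-6 * 2 * pi * 30e3
  expect_equal(max(Mod(fl$u_x)), expected, tolerance = 1e-6)
  expect_equal(min(Mod(fl$u_x)), expected, tolerance = 1e-6)
  expect_lt(max(Mod(fl$u_y)), 1e-12)
  # i*2*pi*f0 times the -pi/2 sine phasor gives a real, positive velocity
  expect_equal(Arg(fl$u_x[60, 60]), 0, tolerance = 1e-9)
  # n forced to 1: constant field equal to the global average phasor
  f1 <- homodyne_flow(tr, sch, 30e3, c(120L, 120L), pitch, n = 1L)
  expect_equal(Mod(f1$u_x[1, 1]), Mod(f1$u_x[120, 60]))
  expect_equal(f1$u_x[1, 1], mean(f1$track_phasors$u_x))
})

test_that("a linear flow ramp is recovered by quadratic interpolation", {
  cfg <- pulse_train_config(30e3, 10e3, n_pulses = 120L)
  sch <- strobe_schedule(cfg)
  set.seed(8)
  base <- expand.grid(x = seq(10, 170, by = 20), y = seq(10, 170, by = 20))
  amp <- 1 + base$x / 180   # linear in x
  tt <- sch$sample_times
  cents <- lapply(seq_along(tt), function(n) {
    s <- sin(2 * pi * 30e3 * tt[n])
    data.frame(x = base$x + amp * s, y = base$y)
  })
  tr <- link_tracks(cents)
  fl <- homodyne_flow(tr, sch, 30e3, c(180L, 180L), 1, n = 3L)
  scale <- 1e-6 * 2 * pi * 30e3
  got <- Mod(strobomech:::bilinear_sample_cplx(
    fl$u_x, base$y + 1, base$x + 1))
  # within the node hull the order-2 interpolant reproduces a linear ramp;
  # outside it the field is clamped to the boundary nodes by design
  hull <- base$x >= min(fl$node_x) & base$x <= max(fl$node_x)
  expect_lt(max(abs(got[hull] / (amp[hull] * scale) - 1)), 0.05)
  clamped <- base$x < min(fl$node_x)
  expect_lt(max(abs(got[clamped] / ((1 + min(fl$node_x) / 180) * scale) - 1)),
            1e-6)
  # the interpolant passes through its nodes exactly
  nx <- fl$node_x; ny <- fl$node_y
  at_nodes <- matrix(strobomech:::quad_interp2(
    nx, ny, fl$node_values$x,
    rep(nx, each = 3), rep(ny, 3)), 3, 3)
  expect_equal(at_nodes, fl$node_values$x, tolerance = 1e-12)
})

test_that("stress law reproduces the expected magnitude and linearity", {
  cfg <- pulse_train_config(30e3, 10e3, n_pulses = 120L)
  sch <- strobe_schedule(cfg)
  base <- expand.grid(x = c(20, 60, 100, 140), y = c(20, 60, 100, 140))
  pitch <- 0.514
  # choose the pixel amplitude that gives |u| = 1 m/s
  A <- 1 / (2 * pi * 30e3) / (pitch * 1e-6)
  cents <- oscillating_centroids(base, amp_px = A, sch, 30e3)
  fl <- homodyne_flow(link_tracks(cents), sch, 30e3, c(160L, 160L), pitch)
  st <- stress_field(fl, mu = 1.002e-3, R_b = 1.5e-6)
  expect_equal(Mod(st$sigma_x[80, 80]), 668, tolerance = 0.001)
  # zero flow -> zero stress
  c0 <- oscillating_centroids(base, amp_px = 0, sch, 30e3)
  st0 <- stress_field(homodyne_flow(link_tracks(c0), sch, 30e3,
                                    c(160L, 160L), pitch))
  expect_equal(max(Mod(st0$sigma_x)), 0, tolerance = 1e-12)
  # a phase shift of the flow shifts the stress phase equally
  cph <- oscillating_centroids(base, amp_px = A, sch, 30e3, phase = 0.7)
  stp <- stress_field(homodyne_flow(link_tracks(cph), sch, 30e3,
                                    c(160L, 160L), pitch),
                      mu = 1.002e-3, R_b = 1.5e-6)
  dphi <- Arg(stp$sigma_x[80, 80] / st$sigma_x[80, 80])
  expect_equal(dphi, 0.7, tolerance = 1e-6)
})

test_that("flow residuals vanish for an exact interpolant and flag outliers", {
  cfg <- pulse_train_config(30e3, 10e3, n_pulses = 120L)
  sch <- strobe_schedule(cfg)
  base <- expand.grid(x = c(15, 45, 75, 105), y = c(15, 45, 75, 105))
  cents <- oscillating_centroids(base, amp_px = 1.5, sch, 30e3)
  tr <- link_tracks(cents)
  fl <- homodyne_flow(tr, sch, 30e3, c(120L, 120L), 0.514, n = 1L)
  res <- flow_residuals(tr, fl)
  expect_lt(res$relative_error, 1e-9)
  expect_length(res$outliers, 0)
  # one track with 10x amplitude dominates and is flagged
  tt <- sch$sample_times
  base2 <- expand.grid(x = c(20, 60, 100, 140), y = c(20, 60, 100, 140))
  cents2 <- lapply(seq_along(tt), function(n) {
    s <- sin(2 * pi * 30e3 * tt[n])
    a <- rep(0.8, nrow(base2)); a[6] <- 8
    data.frame(x = base2$x + a * s, y = base2$y)
  })
  tr2 <- link_tracks(cents2)
  expect_length(complete_ids(tr2), nrow(base2))
  fl2 <- homodyne_flow(tr2, sch, 30e3, c(160L, 160L), 0.514, n = 1L)
  res2 <- flow_residuals(tr2, fl2)
  expect_true(6 %in% res2$outliers)
  expect_gt(res2$relative_error, 0.5)
})
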