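test_that("pulse waveform is the Gaussian-windowed sinusoid", {
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 10L,
                            f_repet = 1000)
  expect_equal(cfg$t0, 5e-4)
  # at t = t0 the envelope is exactly 1 and sin(2 pi * 30e3 * 5e-4) =
  # sin(30 pi) = 0
  expect_equal(as.numeric(synth_pulse(cfg, cfg$t0)), 0, tolerance = 1e-12)
  # a quarter carrier period later the envelope is still ~1
  tq <- cfg$t0 + 1 / (4 * cfg$f0)
  expect_equal(abs(as.numeric(synth_pulse(cfg, tq))),
               exp(-cfg$alpha^2 * (tq - cfg$t0)^2), tolerance = 1e-12)
  # Gaussian decay: three envelope widths out the pulse is below e^-9
  t3 <- cfg$t0 + 3 / cfg$alpha
  expect_lt(abs(as.numeric(synth_pulse(cfg, t3))), exp(-9) + 1e-12)
  expect_error(pulse_train_config(f0 = -1, alpha = 1), "f0")
  expect_error(pulse_train_config(f0 = 1e3, alpha = 0), "alpha")
})

test_that("drive spectrum peaks at the carrier frequency", {
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 10L)
  w <- synth_pulse(cfg)
  tt <- attr(w, "t")
  sp <- Mod(stats::fft(w))
  n <- length(w)
  freqs <- (seq_len(n) - 1) / (n * diff(tt[1:2]))
  pos <- freqs > 0 & freqs <= 1 / (2 * diff(tt[1:2]))
  expect_equal(freqs[pos][which.max(sp[pos])], 30e3, tolerance = 0.02)
})

test_that("strobe schedule satisfies the detuning identities", {
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 1000L,
                            f_repet = 1000)
  sch <- strobe_schedule(cfg)
  expect_equal(sch$f_strob, 1000 * 1000 / 1001)
  expect_equal(sch$dt_effective, 1e-6, tolerance = 1e-12)
  expect_length(sch$sample_times, cfg$n_frames)
  expect_equal(diff(sch$sample_times[1:2]), sch$dt_effective)
  # smallest case
  s1 <- strobe_schedule(pulse_train_config(f0 = 100, alpha = 1,
                                           n_pulses = 1L, f_repet = 1000))
  expect_equal(s1$f_strob, 500)
  expect_equal(s1$dt_effective, 1e-3)
  # the reconstructed time base oversamples a 45 kHz carrier
  cfg45 <- pulse_train_config(f0 = 45e3, alpha = 10e3, n_pulses = 1000L)
  expect_gte(1 / strobe_schedule(cfg45)$dt_effective, 2 * 45e3)
})

test_that("homodyne coefficient follows the stated convention", {
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 1000L,
                            n_frames = 1000L)
  tt <- strobe_schedule(cfg)$sample_times
  A <- 2.5
  cs <- homodyne_coefficient(A * sin(2 * pi * 30e3 * tt), tt, 30e3)
  expect_equal(Mod(cs), A, tolerance = 1e-9)
  expect_equal(Arg(cs), -pi / 2, tolerance = 1e-9)
  cc <- homodyne_coefficient(A * cos(2 * pi * 30e3 * tt), tt, 30e3)
  expect_equal(Arg(cc), 0, tolerance = 1e-9)
  # DC rejection
  expect_equal(Mod(homodyne_coefficient(rep(3.2, 1000), tt, 30e3)), 0,
               tolerance = 1e-10)
  # out-of-band carrier is rejected
  expect_error(homodyne_coefficient(sin(tt), tt, 1e9), "band")
  expect_error(homodyne_coefficient(1:5, c(0, 1, 2, 4, 8), 0.1), "uniform")
})

test_that("FFT-bin extraction equals the direct projection and is linear", {
  cfg <- pulse_train_config(f0 = 30e3, alpha = 10e3, n_pulses = 200L,
                            n_frames = 200L)
  tt <- strobe_schedule(cfg)$sample_times
  n <- length(tt)
  set.seed(11)
  for (rep in 1:10) {
    x <- stats::rnorm(n)
    direct <- homodyne_coefficient(x, tt, 30e3)
    bin <- round(30e3 * n * diff(tt[1:2]))
    viafft <- 2 / n * stats::fft(x)[bin + 1]
    expect_lt(Mod(direct - viafft) / Mod(viafft), 1e-10)
    y <- stats::rnorm(n)
    a <- stats::rnorm(1); b <- stats::rnorm(1)
    lhs <- homodyne_coefficient(a * x + b * y, tt, 30e3)
    rhs <- a * homodyne_coefficient(x, tt, 30e3) +
      b * homodyne_coefficient(y, tt, 30e3)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # matrix input: one coefficient per column
  X <- cbind(sin(2 * pi * 30e3 * tt), cos(2 * pi * 30e3 * tt))
  cm <- homodyne_coefficient(X, tt, 30e3)
  expect_equal(Mod(cm), c(1, 1), tolerance = 1e-9)
})
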