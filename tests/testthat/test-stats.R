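# Minimal box table builder for statistics tests.
mk_table <- function(G_mod, channel, edge = NULL, cell = NULL,
                     loss_frac = 0.5) {
  n <- length(G_mod)
  out <- data.frame(
    x_um = seq_len(n), y_um = seq_len(n), channel = channel,
    G_mod = G_mod, G_storage = G_mod * sqrt(1 - loss_frac^2),
    G_loss = G_mod * loss_frac,
    edge_dist_um = if (is.null(edge)) stats::runif(n, 0, 10) else edge,
    cell = if (is.null(cell)) rep(NA_integer_, n) else cell)
  class(out) <- c("dic_box_table", "data.frame")
  out
}

test_that("Mann-Whitney matches exact references", {
  # two identical samples: p = 1 by symmetry
  p_id <- suppressWarnings(stats::wilcox.test(1:40, 1:40)$p.value)
  expect_equal(p_id, 1)
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1
  wt <- stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(wt$statistic), 0)
  expect_equal(wt$p.value, 0.1)
})

test_that("Mann-Whitney agrees with exhaustive enumeration for small n", {
  # independent oracle: enumerate all assignments of ranks to group 1
  exact_p <- function(x, y) {
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combs <- utils::combn(n + m, n)
    Us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
    mu <- n * m / 2
    mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  }
  set.seed(17)
  for (k in 1:8) {
    n <- sample(3:7, 1); m <- sample(3:7, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(m, mean = 0.5)
    expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 exact_p(x, y), tolerance = 1e-12,
                 info = sprintf("case %d (n=%d, m=%d)", k, n, m))
  }
})

test_that("population summaries and tests separate distinct populations", {
  set.seed(31)
  n <- 200
  g1 <- 4.4e3 * exp(stats::rnorm(n, sd = 0.25)) * (1 + stats::rnorm(n, sd = 0.15))
  g2 <- 6.3e3 * exp(stats::rnorm(n, sd = 0.25)) * (1 + stats::rnorm(n, sd = 0.15))
  tb <- mk_table(c(g1, g2), rep(c("green", "orange"), each = n))
  ps <- population_stats(tb)
  s <- ps$summary[ps$summary$measure == "G_mod", ]
  expect_equal(s$median[s$group == "green"], stats::median(g1))
  expect_equal(s$mean[s$group == "orange"], mean(g2))
  expect_equal(s$sem[s$group == "green"], stats::sd(g1) / sqrt(n))
  expect_equal(s$q1[s$group == "green"],
               unname(stats::quantile(g1, 0.25)))
  expect_lt(ps$tests$G_mod["green", "orange"], 1e-3)
  # lognormal-like data: non-normal by Shapiro-Wilk
  expect_lt(max(ps$shapiro$shapiro_p[ps$shapiro$measure == "G_mod"]), 0.01)
  # single group: summaries only
  ps1 <- population_stats(tb[tb$channel == "green", ])
  expect_null(ps1$tests)
})

test_that("edge profiles are flat for uniform scenes and track gradients", {
  set.seed(12)
  n <- 600
  edge <- stats::runif(n, 0, 12)
  tb <- mk_table(5000 * (1 + stats::rnorm(n, sd = 0.1)),
                 rep("green", n), edge = edge)
  pr <- edge_profile(tb, bin_width = 3)
  expect_true(all(abs(pr$mean - 5000) < 4 * pr$sem))
  # centre softened: modulus increases towards the edge (decreasing depth)
  tb2 <- mk_table(5000 / (1 + edge / 12) * (1 + stats::rnorm(n, sd = 0.05)),
                  rep("green", n), edge = edge)
  pr2 <- edge_profile(tb2, bin_width = 3)
  expect_true(all(diff(pr2$mean) < 0))   # deeper bins are softer
  # empty table: empty profile, no error
  pr0 <- edge_profile(mk_table(numeric(0), character(0), edge = numeric(0)))
  expect_equal(nrow(pr0), 0)
})

test_that("loss-storage density concentrates on the identity line", {
  tb <- mk_table(exp(stats::runif(300, 7, 9.5)), rep("green", 300),
                 loss_frac = 1 / sqrt(2))  # G' = G''
  lv <- loss_vs_storage(tb)
  expect_equal(lv$pairs$G_storage, lv$pairs$G_loss, tolerance = 1e-12)
  expect_true(all(is.finite(lv$pairs$density)))
  # robust at tiny n
  lv2 <- loss_vs_storage(mk_table(c(3000, 5000), rep("g", 2)))
  expect_equal(nrow(lv2$pairs), 2)
})

test_that("blank strain noise guards its preconditions", {
  n <- 60L
  sch <- strobe_schedule(pulse_train_config(30e3, 10e3, n_pulses = 10L))
  gam <- matrix(0.02 + 0i, 11, 11)
  st <- structure(list(gamma_p = gam, gamma_s = gam,
                       box_x = seq(2, 52, by = 5), box_y = seq(2, 52, by = 5),
                       box_size = 5L, spacing = 2.57, pixel_pitch = 0.514,
                       image_size = c(n, n)),
                  class = "strain_maps")
  cellm <- matrix(FALSE, n, n); cellm[1:28, ] <- TRUE
  blankm <- !cellm
  expect_error(blank_strain_noise(st, cellm, cellm), "overlaps")
  out <- suppressWarnings(blank_strain_noise(st, blankm, cellm))
  expect_equal(out$rel_strain_error, 1)   # identical strain everywhere
  # zero strain in the blank region
  st0 <- st
  st0$gamma_p[7:11, ] <- 0; st0$gamma_s[7:11, ] <- 0
  out0 <- suppressWarnings(blank_strain_noise(st0, blankm, cellm))
  expect_equal(out0$rel_strain_error, 0)
})

test_that("error propagation and depth-of-field bounds are the stated arithmetic", {
  expect_equal(propagate_errors(0.30, 0.05), 0.304, tolerance = 5e-4)
  expect_equal(propagate_errors(0.123, 0), 0.123)
  expect_equal(propagate_errors(0.3, 0.4), 0.5)
  # symmetric and monotone
  set.seed(2)
  for (i in 1:5) {
    a <- stats::runif(1); b <- stats::runif(1)
    expect_equal(propagate_errors(a, b), propagate_errors(b, a))
    expect_gte(propagate_errors(a + 0.1, b), propagate_errors(a, b))
  }
  expect_equal(depth_of_field_bias(0.87, 1.5), 0.58)
  expect_equal(depth_of_field_bias(0, 1.5), 0)
  expect_equal(depth_of_field_bias(1.5, 1.5), 1)
  bud <- error_budget(0.30, 0.05)
  expect_equal(bud$rel_modulus_error,
               sqrt(bud$rel_flow_error^2 + bud$rel_strain_error^2))
})

test_that("cell aggregation preserves group means", {
  set.seed(9)
  cellid <- rep(1:10, each = 30)
  g <- 5000 + 400 * stats::rnorm(10)[cellid] + stats::rnorm(300, sd = 100)
  tb <- mk_table(g, rep("green", 300), cell = cellid)
  cmp <- compare_box_cell_stats(tb)
  expect_equal(cmp$n_cells, 10)
  expect_equal(cmp$mean_ds, mean(g))
  agg <- tapply(g, cellid, mean)
  expect_equal(cmp$mean_cs, mean(agg))
  expect_gt(cmp$mw_p, 0.05)
})
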