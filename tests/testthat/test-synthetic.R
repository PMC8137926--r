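test_that("noiseless reliable cell puts every lap's COM at the true center", {
  b <- quick_behavior(n_laps = 15, seed = 2, cv = 0)
  cell <- quick_cell(center = 150, width = 60)
  out <- synthesize_cell(cell, b, noise_sigma = 0, seed = 3)
  m <- raw_matrix(out$dff, b)
  cd <- com_per_lap(m)
  expect_equal(nrow(cd), 15)          # one transient per lap
  expect_true(all(abs(cd$com - 150) <= 3))  # within half a bin
})

test_that("drifting envelope is recovered by regression on lap-wise COMs", {
  b <- quick_behavior(n_laps = 30, seed = 4, cv = 0)
  cell <- quick_cell(center = 180, width = 50, drift = -0.5)
  out <- synthesize_cell(cell, b, noise_sigma = 0, seed = 5)
  cd <- com_per_lap(raw_matrix(out$dff, b))
  fit <- field_shift_regression(cd)
  # independent oracle: OLS on the ground-truth envelope centers
  truth_centers <- 180 - 0.5 * (cd$lap - 1)
  oracle <- lm(truth_centers ~ cd$lap)
  expect_equal(unname(coef(oracle)[2]), -0.5, tolerance = 1e-12)
  expect_equal(fit$slope_cm_per_lap, -0.5, tolerance = 0.05)
})

test_that("silent and degenerate cells behave", {
  b <- quick_behavior(n_laps = 5, seed = 1)
  mute <- quick_cell(reliability = 0)
  out <- synthesize_cell(mute, b, noise_sigma = 0, seed = 2)
  expect_true(all(out$dff == 0))  # no field, no out-of-field events, no noise
  # empty session: valid behavior, 0-row dff
  s0 <- synthesize_session(behavior_config(n_laps = 5), list(), seed = 3)
  expect_equal(nrow(s0$dff), 0)
  expect_equal(s0$behavior$n_laps, 5)
})

test_that("sessions are reproducible and stable under population growth", {
  cfg <- behavior_config(n_laps = 6)
  cells <- list(quick_cell(center = 60), quick_cell(center = 200))
  s1 <- synthesize_session(cfg, cells, seed = 11)
  s2 <- synthesize_session(cfg, cells, seed = 11)
  expect_identical(s1$dff, s2$dff)
  # child seeds: first cell's trace unchanged when a cell is appended
  s3 <- synthesize_session(cfg, c(cells, list(quick_cell(center = 120))),
                           seed = 11)
  expect_identical(s3$dff[1, ], s1$dff[1, ])
})

test_that("drift off the track truncates the envelope and flags the cell", {
  b <- quick_behavior(n_laps = 30, seed = 6, cv = 0)
  edge <- quick_cell(center = 8, width = 40, drift = -1)
  out <- synthesize_cell(edge, b, noise_sigma = 0, seed = 7)
  expect_true(out$truth$clipped)
  expect_true(all(is.finite(out$dff)))
})

test_that("preset onset distributions match their design", {
  # instant-rich preset: lap-1 fraction within binomial CI of 0.30
  t1 <- preset_truth("ca1_day1", n_cells = 400, seed = 21)
  frac <- mean(vapply(t1, function(x) x$onset_laps[1], numeric(1)) == 1)
  ci <- qbinom(c(0.005, 0.995), 400, 0.30) / 400
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])

  # delayed preset: onset histogram flat by chi-square at alpha = 0.01
  t3 <- preset_truth("ca3_day1", n_cells = 400, seed = 22)
  on3 <- vapply(t3, function(x) x$onset_laps[1], numeric(1))
  tab <- tabulate(on3, nbins = 18)
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
  # and its lap-1 fraction is near 9%
  expect_lt(mean(on3 == 1), 0.16)
  expect_error(preset_truth("nope", 5), "available")
})

test_that("paired days reuse, remap, or silence cells by fate", {
  cfg <- behavior_config(n_laps = 25)
  cells <- lapply(seq(40, 260, length.out = 6), function(ctr) {
    quick_cell(center = ctr, width = 50)
  })
  # all stable, no drift: across-day map correlation > 0.5 everywhere
  pair <- synthesize_paired_days(cfg, cells, stable_fraction = 1, seed = 31,
                                 noise_sigma = 0.02)
  expect_identical(pair,
                   synthesize_paired_days(cfg, cells, stable_fraction = 1,
                                          seed = 31, noise_sigma = 0.02))
  rs <- vapply(seq_along(cells), function(i) {
    m1 <- raw_matrix(pair$day1$dff[i, ], pair$day1$behavior)
    m2 <- raw_matrix(pair$day2$dff[i, ], pair$day2$behavior)
    across_day_stability(m1, m2)$r
  }, numeric(1))
  expect_true(all(rs > 0.5))

  # full remap: correlations collapse
  pair0 <- synthesize_paired_days(cfg, cells, stable_fraction = 0, seed = 32,
                                  noise_sigma = 0.02)
  rs0 <- vapply(seq_along(cells), function(i) {
    m1 <- raw_matrix(pair0$day1$dff[i, ], pair0$day1$behavior)
    m2 <- raw_matrix(pair0$day2$dff[i, ], pair0$day2$behavior)
    across_day_stability(m1, m2)$r
  }, numeric(1))
  expect_lte(median(rs0, na.rm = TRUE), 0.2)
})

test_that("stable fraction of a mixed cohort is recovered within binomial CI", {
  set.seed(41)
  cells <- lapply(1:120, function(i) quick_cell(center = runif(1, 30, 270),
                                                width = 55))
  cfg <- behavior_config(n_laps = 25)
  pair <- synthesize_paired_days(cfg, cells, stable_fraction = 0.64,
                                 seed = 42, noise_sigma = 0.02)
  stable <- vapply(seq_along(cells), function(i) {
    m1 <- raw_matrix(pair$day1$dff[i, ], pair$day1$behavior)
    m2 <- raw_matrix(pair$day2$dff[i, ], pair$day2$behavior)
    isTRUE(across_day_stability(m1, m2)$stable)
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), 120, 0.64) / 120
  expect_gte(mean(stable), ci[1])
  expect_lte(mean(stable), ci[2])
})
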