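test_that("lap-by-bin matrix equals a brute-force per-sample accumulation", {
  b <- quick_behavior(n_laps = 8, seed = 13)
  set.seed(14)
  trace <- abs(rnorm(length(b$time_s), 0, 0.3))
  m <- lap_bin_matrix(trace, b, n_bins = 50)
  # independent oracle: explicit loops over samples
  bw <- 6
  mask <- b$velocity_cm_s >= 0.2 & !b$is_pause
  oracle <- matrix(0, 8, 50)
  for (lap in 1:8) for (bin in 1:50) {
    sel <- mask & b$lap_index == lap &
      b$position_cm >= (bin - 1) * bw & b$position_cm < bin * bw
    if (bin == 50) sel <- sel | (mask & b$lap_index == lap &
                                   b$position_cm >= 300)
    if (any(sel)) oracle[lap, bin] <- mean(trace[sel])
  }
  expect_equal(unclass(m)[, ], oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("constant activity while running fills the matrix with that constant", {
  b <- quick_behavior(n_laps = 4, seed = 15)
  m <- lap_bin_matrix(rep(0.7, length(b$time_s)), b)
  expect_true(all(abs(m[attr(m, "occupancy") > 0] - 0.7) < 1e-12))
})

test_that("candidate detection finds boxcars, separates bumps, and matches a threshold oracle", {
  # single boxcar on zero background
  mm <- numeric(50); mm[20:27] <- 1
  cand <- detect_candidates(mm)
  expect_equal(cand, data.frame(bin_start = 20L, bin_end = 27L))

  # two separated bumps, ordered by position
  mm2 <- numeric(50); mm2[5:9] <- 0.8; mm2[30:38] <- 1
  cand2 <- detect_candidates(mm2)
  expect_equal(nrow(cand2), 2)
  expect_true(cand2$bin_start[1] < cand2$bin_start[2])

  # flat map: no candidates
  expect_equal(nrow(detect_candidates(rep(0.3, 50))), 0)

  # threshold equals an independent sort-and-mean recomputation
  set.seed(16)
  for (i in 1:20) {
    mm3 <- abs(rnorm(50, 0, 0.2)) + 0.6 * exp(-((1:50) - sample(50, 1))^2 / 18)
    baseline <- mean(sort(mm3)[1:12])
    thr <- baseline + 0.15 * (max(mm3) - baseline)
    cand3 <- detect_candidates(mm3)
    inside <- rep(FALSE, 50)
    for (k in seq_len(nrow(cand3))) inside[cand3$bin_start[k]:cand3$bin_end[k]] <- TRUE
    expect_identical(inside, mm3 > thr)
  }
})

test_that("the four field criteria enforce their boundaries", {
  cfg <- pf_config()
  nl <- 30
  mk <- function(s, e, level, out = 0, laps = nl) {
    v <- matrix(out, nl, 50)
    v[seq_len(laps), s:e] <- level
    toy_matrix(v)
  }
  # 18 cm (3 bins) fails width; 24 cm (4 bins) passes
  expect_false(apply_criteria(data.frame(bin_start = 10L, bin_end = 12L),
                              mk(10, 12, 1), cfg)$width_ok)
  expect_true(apply_criteria(data.frame(bin_start = 10L, bin_end = 13L),
                             mk(10, 13, 1), cfg)$width_ok)
  # in/out ratio 2.5 fails the >3 criterion
  chk <- apply_criteria(data.frame(bin_start = 10L, bin_end = 19L),
                        mk(10, 19, 0.3, out = 0.12), cfg)
  expect_false(chk$ratio_ok)
  # activity on exactly 15 of 30 laps passes the occupancy boundary
  chk15 <- apply_criteria(data.frame(bin_start = 10L, bin_end = 19L),
                          mk(10, 19, 1, laps = 15), cfg)
  expect_true(chk15$laps_ok)
  chk14 <- apply_criteria(data.frame(bin_start = 10L, bin_end = 19L),
                          mk(10, 19, 1, laps = 14), cfg)
  expect_false(chk14$laps_ok)
  # peak criterion: 0.1 dF/F is not enough, must exceed it
  expect_false(apply_criteria(data.frame(bin_start = 10L, bin_end = 19L),
                              mk(10, 19, 0.1), cfg)$peak_ok)
})

test_that("bootstrap accepts a strong reliable field and its inputs are validated", {
  b <- quick_behavior(n_laps = 30, seed = 17, cv = 0)
  out <- synthesize_cell(quick_cell(center = 120, width = 60), b,
                         noise_sigma = 0.04, seed = 18)
  tr <- detect_transients(out$dff, b$frame_rate_hz)
  m <- lap_bin_matrix(tr$sig_trace, b)
  f <- detect_place_fields(m, seed = 19)
  expect_true(any(f$significant))
  expect_lte(min(f$p_boot, na.rm = TRUE), 0.05)
  expect_error(bootstrap_pvalue(m, f[1, ], n_iter = 0), "n_iter")
  expect_warning(bootstrap_pvalue(m, f[1, ], n_iter = 50, seed = 1),
                 "unstable")
})

test_that("detection is translation-equivariant away from track edges", {
  b <- quick_behavior(n_laps = 30, seed = 20, cv = 0)
  out <- synthesize_cell(quick_cell(center = 100, width = 50), b,
                         noise_sigma = 0, seed = 21)
  m <- lap_bin_matrix(out$dff, b)
  f0 <- detect_place_fields(m, seed = 22)
  k <- 10  # shift all activity 10 bins (60 cm) forward
  m_shift <- toy_matrix(m[, c(41:50, 1:40)][, ])
  f1 <- detect_place_fields(m_shift, seed = 22)
  expect_equal(f1$bin_start, f0$bin_start + k)
  expect_equal(f1$bin_end, f0$bin_end + k)
})

test_that("edge-clipping rule matches its stated boundaries", {
  # centered field: not clipped
  expect_false(is_edge_clipped(150, 60))
  # field near the start: 12 <= 30 - 6
  expect_true(is_edge_clipped(12, 60))
  # boundary inclusive: COM exactly at half-width minus one bin
  expect_true(is_edge_clipped(24, 60))
  expect_false(is_edge_clipped(25, 60))
})

test_that("event-to-field masking keeps whole transients by peak position", {
  b <- quick_behavior(n_laps = 6, seed = 23, cv = 0)
  out <- synthesize_cell(quick_cell(center = 150, width = 50), b,
                         noise_sigma = 0, seed = 24)
  tr <- detect_transients(out$dff, b$frame_rate_hz)
  # all events peak inside a wide extent: identity
  all_in <- mask_to_field(tr, c(60, 240), b)
  expect_equal(nrow(all_in$events), nrow(tr$events))
  expect_equal(all_in$sig_trace, tr$sig_trace)
  # extent elsewhere: nothing retained
  none <- mask_to_field(tr, c(0, 60), b)
  expect_equal(nrow(none$events), 0)
  expect_true(all(none$sig_trace == 0))
  # straddling: peak just inside a boundary keeps the whole event
  pos <- event_positions(tr, b)
  cut <- pos$peak_pos_cm[1] + 0.5
  kept <- mask_to_field(tr, c(cut - 10, cut), b)
  expect_true(tr$events$onset[1] %in% kept$events$onset)
  dropped <- mask_to_field(tr, c(cut, cut + 10), b)
  expect_false(tr$events$onset[1] %in% dropped$events$onset)
})
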