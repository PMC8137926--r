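test_that("shift regression recovers a perfect line and matches a normal-equations oracle", {
  laps <- 1:20
  cd <- data.frame(lap = laps, com = 100 - 0.5 * laps, peak = 1)
  fit <- field_shift_regression(cd)
  expect_equal(fit$slope_cm_per_lap, -0.5, tolerance = 1e-12)
  expect_equal(fit$shift_class, "backward")
  expect_lt(fit$p_value, 1e-10)

  # closed-form OLS against lm() on noisy data
  set.seed(40)
  for (i in 1:50) {
    x <- sort(sample(1:40, 12))
    y <- rnorm(12, 50 + 0.3 * x, 2)
    fit <- field_shift_regression(data.frame(lap = x, com = y, peak = 1))
    ref <- summary(lm(y ~ x))
    expect_equal(fit$slope_cm_per_lap, unname(coef(ref)[2, 1]),
                 tolerance = 1e-10)
    expect_equal(fit$p_value, unname(coef(ref)[2, 4]), tolerance = 1e-9)
  }

  # too few active laps: excluded, not fit
  short <- field_shift_regression(data.frame(lap = 1:4, com = 1:4, peak = 1))
  expect_true(short$excluded)
  expect_equal(short$shift_class, "excluded")
})

test_that("F-test type-I error on stationary fields stays near the nominal level", {
  set.seed(41)
  sig <- vapply(1:150, function(i) {
    cd <- data.frame(lap = 1:30, com = rnorm(30, 150, 3), peak = 1)
    field_shift_regression(cd)$p_value < 0.05
  }, logical(1))
  expect_lte(sum(sig), qbinom(0.999, 150, 0.05))
})

test_that("session shift is exact under linear drift and zero when stationary", {
  cd0 <- data.frame(lap = 1:30, com = rep(120, 30), peak = runif(30, 0.5, 1))
  expect_equal(as.numeric(session_shift(cd0)), 0)
  for (d in c(-0.4, 0.25)) {
    cd <- data.frame(lap = 1:30, com = 120 + d * (1:30),
                     peak = runif(30, 0.5, 1.5))
    expect_equal(as.numeric(session_shift(cd)), d, tolerance = 1e-9)
  }
  # backward drift gives a negative value
  expect_lt(as.numeric(session_shift(
    data.frame(lap = 1:30, com = 120 - 0.3 * (1:30), peak = 1))), 0)
  # short series: windows truncated and flagged
  s <- session_shift(data.frame(lap = 1:6, com = 1:6, peak = 1))
  expect_true(attr(s, "truncated"))
})

test_that("lap-shuffle null is centered and detects a drifting population", {
  set.seed(42)
  drifting <- lapply(1:60, function(i) {
    data.frame(lap = 1:25, com = rnorm(25, 150 - 0.3 * (1:25), 3), peak = 1)
  })
  out <- lap_shuffle_null(drifting, n_shuffles = 200, seed = 43)
  # exchangeable null: mean near 0
  expect_lt(abs(mean(out$null_mean)),
            2 * sd(out$null_mean) / sqrt(length(out$null_mean)) + 0.02)
  # observed mean below the null 95% interval
  expect_lt(mean(out$observed), quantile(out$null_mean, 0.025))
  # estimation contrast excludes 0
  expect_lt(out$estimation$ci_high, 0)
  # reproducible
  out2 <- lap_shuffle_null(drifting, n_shuffles = 200, seed = 43)
  expect_identical(out$null_mean, out2$null_mean)
})

test_that("population shift curve is pinned at the reference lap and linear under homogeneous drift", {
  d <- -0.35
  series <- lapply(1:20, function(i) {
    data.frame(lap = 1:30, com = 100 + i + d * (1:30), peak = 1)
  })
  onsets <- rep(1L, 20)
  pc <- population_shift_curve(series, onsets)
  expect_equal(pc$curve$mean[pc$curve$lap == 12], 0)
  expect_true(all(abs(pc$points$shift[pc$points$lap == 12]) < 1e-12))
  # untruncated laps lie exactly on the line through (12, 0)
  full <- pc$curve$lap <= 30 - 4
  expect_equal(pc$curve$mean[full], d * (pc$curve$lap[full] - 12),
               tolerance = 1e-9)
  # the window truncates at the session end, so the pooled slope is very
  # slightly attenuated relative to the generating drift
  expect_equal(pc$slope, d, tolerance = 0.1 * abs(d))
  # stationary population: flat curve, slope 0
  flat <- lapply(1:20, function(i) {
    data.frame(lap = 1:30, com = rep(100 + i, 30), peak = 1)
  })
  pc0 <- population_shift_curve(flat, onsets)
  expect_equal(pc0$slope, 0, tolerance = 1e-12)
  expect_true(all(abs(pc0$curve$mean) < 1e-12))
  # unsmoothed variant keeps the slope sign
  pc1 <- population_shift_curve(series, onsets, window = 1)
  expect_equal(sign(pc1$slope), sign(pc$slope))
  expect_equal(pc1$slope, d, tolerance = 1e-9)
})

test_that("population curve inclusion rule filters late onsets and silent reference laps", {
  series <- list(
    data.frame(lap = 1:30, com = 100, peak = 1),
    data.frame(lap = 15:30, com = 100, peak = 1),   # no lap-12 activity
    data.frame(lap = 1:30, com = 100, peak = 1))
  pc <- population_shift_curve(series, onsets = c(1L, 1L, 25L))
  expect_equal(pc$n_fields, 1)
  expect_error(population_shift_curve(series[2], onsets = 1L),
               "inclusion")
})

test_that("resampled slope comparison separates different drifts and not identical ones", {
  set.seed(44)
  mk_pop <- function(d, n) {
    series <- lapply(1:n, function(i) {
      data.frame(lap = 1:30, com = rnorm(30, 150 + d * (1:30), 3), peak = 1)
    })
    population_shift_curve(series, rep(1L, n))$points
  }
  a <- mk_pop(-0.5, 60)
  b <- mk_pop(0, 40)
  cmp <- resampled_slope_comparison(list(a = a, b = b), n_resamples = 200,
                                    seed = 45)
  expect_false(cmp$overlap["a", "b"])
  expect_true(all(cmp$slopes[, "a"] < min(cmp$slopes[, "b"])))
  # a population against itself: full overlap, matched size = smaller count
  cmp2 <- resampled_slope_comparison(list(x = a, y = a), n_resamples = 200,
                                     seed = 46)
  expect_true(cmp2$overlap["x", "y"])
  expect_equal(cmp2$n_matched, 60)
  # deterministic under seed
  cmp3 <- resampled_slope_comparison(list(a = a, b = b), n_resamples = 200,
                                     seed = 45)
  expect_identical(cmp$slopes, cmp3$slopes)
})

test_that("across-day shift is zero for a replayed day and reset opposes day-1 drift", {
  day1 <- lapply(1:10, function(i) {
    data.frame(lap = 1:25, com = 150 - 0.5 * (0:24), peak = 1)
  })
  # day 2 replays the day-1 end state
  replay <- lapply(1:10, function(i) {
    data.frame(lap = 1:25, com = rep(150 - 0.5 * 24, 25), peak = 1)
  })
  out <- across_day_shift(day1, replay)
  expect_true(all(abs(out$table$offline_shift_cm) < 1e-12))
  # day 2 resets to the original position: offline shift opposes day-1 drift
  reset <- lapply(1:10, function(i) {
    data.frame(lap = 1:25, com = rep(150, 25), peak = 1)
  })
  out2 <- across_day_shift(day1, reset)
  expect_true(all(out2$table$offline_shift_cm > 0))  # opposite of backward
  # unmatched fields are counted, not crashed on
  out3 <- across_day_shift(c(day1, list(NULL)), c(replay, list(NULL)))
  expect_equal(out3$n_unmatched, 1)
})
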