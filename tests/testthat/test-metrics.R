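test_that("lap-wise COM matches hand-evaluated weighted means", {
  # DF = [1, 3] at x = [3, 9] -> COM = 7.5
  m <- toy_matrix(matrix(c(1, 3, rep(0, 48)), 1, 50, byrow = TRUE))
  cd <- com_per_lap(m, data.frame(bin_start = 1L, bin_end = 2L))
  expect_equal(cd$com, 7.5)
  expect_equal(cd$peak, 3)

  # uniform profile: COM at the field midpoint
  m2 <- toy_matrix(matrix(c(rep(0, 9), rep(2, 10), rep(0, 31)), 1, 50,
                          byrow = TRUE))
  cd2 <- com_per_lap(m2, data.frame(bin_start = 10L, bin_end = 19L))
  expect_equal(cd2$com, mean(attr(m2, "bin_centers_cm")[10:19]))

  # single nonzero bin: COM at that bin center; inactive laps absent
  m3 <- toy_matrix(rbind(c(rep(0, 24), 5, rep(0, 25)), rep(0, 50)))
  cd3 <- com_per_lap(m3, data.frame(bin_start = 20L, bin_end = 30L))
  expect_equal(cd3$lap, 1L)
  expect_equal(cd3$com, attr(m3, "bin_centers_cm")[25])
})

test_that("weighted COM and spatial precision match hand evaluation", {
  expect_equal(weighted_com(c(10, 20), c(1, 3)), 17.5)
  expect_equal(weighted_com(c(10, 20), c(2, 2)), 15)
  expect_equal(weighted_com(5, 1), 5)
  expect_error(weighted_com(c(1, 2), c(0, 0)), "undefined")

  # COM = [10, 20], equal peaks: weighted SD = 5, SP = 0.2
  expect_equal(spatial_precision(c(10, 20), c(1, 1)), 0.2)
  # scale invariance in the weights
  expect_equal(spatial_precision(c(10, 20), c(2, 2)), 0.2)
  # zero variance: infinite precision sentinel
  expect_equal(spatial_precision(c(15, 15), c(1, 2)), Inf)
  expect_error(spatial_precision(10, 1), ">= 2")
})

test_that("skewness is zero for symmetric, sign-flips on mirroring, matches a moment oracle", {
  sym <- toy_matrix(matrix(c(rep(0, 10), 1, 2, 4, 2, 1, rep(0, 35)), 1, 50,
                           byrow = TRUE))
  f <- data.frame(bin_start = 11L, bin_end = 15L)
  expect_lt(abs(skewness_per_lap(sym, f)$skew), 1e-10)

  right <- toy_matrix(matrix(c(rep(0, 10), 4, 2, 1, rep(0, 37)), 1, 50,
                             byrow = TRUE))
  fr <- data.frame(bin_start = 11L, bin_end = 13L)
  sk_r <- skewness_per_lap(right, fr)$skew
  # independent brute-force moment computation
  df <- c(4, 2, 1); x <- attr(right, "bin_centers_cm")[11:13]
  w <- df / sum(df); com <- sum(w * x); s <- sqrt(sum(w * (x - com)^2))
  expect_equal(sk_r, sum(w * ((x - com) / s)^3), tolerance = 1e-12)
  expect_gt(sk_r, 0)

  left <- toy_matrix(matrix(c(rep(0, 10), 1, 2, 4, rep(0, 37)), 1, 50,
                            byrow = TRUE))
  expect_equal(skewness_per_lap(left, fr)$skew, -sk_r, tolerance = 1e-12)

  # invariance to positive rescaling of the lap vector
  expect_equal(skewness_per_lap(toy_matrix(right[, , drop = FALSE] * 7), fr)$skew,
               sk_r, tolerance = 1e-12)
})

test_that("lap-wise width counts the inclusive bin span and normalizes to mean 1", {
  m <- toy_matrix(rbind(c(rep(0, 9), rep(1, 5), rep(0, 36)),    # bins 10..14
                        c(rep(0, 9), 1, 0, 1, rep(0, 38))))     # bins 10..12
  f <- data.frame(bin_start = 8L, bin_end = 20L)
  w <- width_per_lap(m, f)
  expect_equal(w$width_cm, c(30, 18))  # 5 and 3 bins x 6 cm
  expect_equal(mean(w$width_norm), 1)
  expect_equal(w$width_norm, c(30, 18) / 24)
  # widths [24, 36] normalize to [0.8, 1.2]
  m2 <- toy_matrix(rbind(c(rep(0, 9), rep(1, 4), rep(0, 37)),
                         c(rep(0, 9), rep(1, 6), rep(0, 35))))
  expect_equal(width_per_lap(m2, f)$width_norm, c(0.8, 1.2))
})

test_that("out/in ratio matches hand evaluation and flags degenerate fields", {
  v <- matrix(0.1, 2, 50)
  v[, 10:19] <- 0.4
  m <- toy_matrix(v)
  f <- data.frame(bin_start = 10L, bin_end = 19L)
  expect_equal(out_in_ratio(m, f), 0.25)
  # zero outside
  v0 <- matrix(0, 2, 50); v0[, 10:19] <- 0.4
  expect_equal(out_in_ratio(toy_matrix(v0), f), 0)
  # uniform everywhere: ratio 1
  expect_equal(out_in_ratio(toy_matrix(matrix(0.2, 2, 50)), f), 1)
  expect_error(out_in_ratio(toy_matrix(matrix(0, 2, 50)), f), "undefined")
})

test_that("onset-lap scan follows the 3-of-6 rule and matches a brute-force oracle", {
  act <- function(laps, n = 30) { v <- rep(FALSE, n); v[laps] <- TRUE; v }
  # transients on every lap: onset 1
  expect_equal(onset_lap(act(1:30)), 1L)
  # {4,5,7}: 3 of laps 4-9 active -> onset 4
  expect_equal(onset_lap(act(c(4, 5, 7))), 4L)
  # {2,10,11,12}: lap 2's window has only 1 active -> onset 10
  expect_equal(onset_lap(act(c(2, 10, 11, 12))), 10L)
  # no qualifying lap
  expect_true(is.na(onset_lap(act(c(2, 20)))))
  # window truncation at session end counts missing laps as inactive
  expect_true(is.na(onset_lap(act(c(28, 29, 30), n = 30), rule = 4)))

  # brute-force oracle over random cases, including the 2-of-6/4-of-6 variants
  set.seed(30)
  oracle <- function(v, rule, window) {
    for (l in seq_along(v)) {
      if (!v[l]) next
      if (sum(v[l:min(l + window - 1, length(v))]) >= rule) return(l)
    }
    NA_integer_
  }
  for (i in 1:200) {
    v <- runif(25) < 0.3
    for (rule in c(2, 3, 4)) {
      expect_identical(onset_lap(v, rule = rule), oracle(v, rule, 6))
    }
  }
})

test_that("onset variants preserve the ordering of instant-rich vs delayed onset distributions", {
  set.seed(31)
  draw_onsets <- function(p1, n) {
    emitted <- lapply(seq_len(n), function(i) {
      o <- if (runif(1) < p1) 1L else sample(2:15, 1)
      stats::runif(30) < 0.9 & seq_len(30) >= o
    })
    sapply(c(2, 3, 4), function(rule) {
      vapply(emitted, function(v) {
        x <- onset_lap(v, rule = rule)
        if (is.na(x)) 30L else x
      }, integer(1))
    })
  }
  rich <- draw_onsets(0.5, 120)
  delayed <- draw_onsets(0.05, 120)
  for (j in 1:3) {
    ks <- suppressWarnings(ks.test(rich[, j], delayed[, j]))
    expect_lt(mean(rich[, j]), mean(delayed[, j]))  # same ordering each rule
    expect_lt(ks$p.value, 0.05)
  }
})
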