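## closed-form simple OLS with F-test; matches lm()/anova() to rounding
ols_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(slope = NA_real_, intercept = NA_real_,
                            p = NA_real_, n = n))
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - my)^2)
  p <- if (n > 2 && sse > 0) {
    f <- (sst - sse) / (sse / (n - 2))
    pf(f, 1, n - 2, lower.tail = FALSE)
  } else if (n > 2 && sst > 0) 0 else NA_real_
  list(slope = slope, intercept = intercept, p = p, n = n)
}

#' Per-field COM shift regression
#'
#' Ordinary least squares of the lap-wise COM_n on lap number (active laps
#' only), with significance from the regression F test. Fields are classed
#' `"backward"` (negative slope, i.e. against the running direction),
#' `"forward"`, or `"nonsignificant"` at p >= 0.05.
#'
#' @param com_df data.frame `lap`, `com` (from [com_per_lap()]); a `peak`
#'   column is used by the smoothed variant.
#' @param min_laps minimum active laps; fewer returns an excluded result.
#' @param p_threshold significance level for the classification.
#' @param smoothed regress on the 5-lap sliding weighted COM instead of the
#'   raw series.
#' @param window sliding-window length for the smoothed variant.
#' @return An object of class `"pf_shift"`: `slope_cm_per_lap`, `intercept`,
#'   `p_value`, `shift_class`, `n_laps`, `excluded`.
#' @export
field_shift_regression <- function(com_df, min_laps = 5, p_threshold = 0.05,
                                   smoothed = FALSE, window = 5) {
  if (smoothed) {
    sl <- sliding_weighted_com(com_df, window)
    com_df <- data.frame(lap = sl$lap, com = sl$com)
  }
  if (nrow(com_df) < min_laps) {
    return(structure(list(slope_cm_per_lap = NA_real_, intercept = NA_real_,
                          p_value = NA_real_, shift_class = "excluded",
                          n_laps = nrow(com_df), excluded = TRUE),
                     class = "pf_shift"))
  }
  fit <- ols_fit(com_df$lap, com_df$com)
  cls <- if (is.na(fit$p) || fit$p >= p_threshold) "nonsignificant"
         else if (fit$slope < 0) "backward" else "forward"
  structure(list(slope_cm_per_lap = fit$slope, intercept = fit$intercept,
                 p_value = fit$p, shift_class = cls, n_laps = fit$n,
                 excluded = FALSE),
            class = "pf_shift")
}

#' @export
print.pf_shift <- function(x, ...) {
  if (x$excluded) {
    cat("pf_shift: excluded (", x$n_laps, "active laps )\n")
  } else {
    cat(sprintf("pf_shift: slope %.3f cm/lap, p = %.3g (%s), %d laps\n",
                x$slope_cm_per_lap, x$p_value, x$shift_class, x$n_laps))
  }
  invisible(x)
}

#' @export
coef.pf_shift <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope_cm_per_lap)
}

## weighted COM over a calendar-lap window [l, l + window - 1]
window_com <- function(com_df, l, window) {
  sel <- com_df$lap >= l & com_df$lap <= l + window - 1L
  if (!any(sel)) return(NA_real_)
  weighted_com(com_df$com[sel], com_df$peak[sel])
}

## 5-lap sliding weighted COM series (current and next window-1 laps),
## truncated to available laps at the series end
sliding_weighted_com <- function(com_df, window = 5) {
  laps <- sort(unique(com_df$lap))
  com <- vapply(laps, function(l) window_com(com_df, l, window), numeric(1))
  data.frame(lap = laps, com = com)
}

#' Session shift of one field
#'
#' The difference between the field's COM at the end and at the onset of the
#' session, each taken as the amplitude-weighted average over a five-lap
#' window (the onset lap and the four following; the last active lap and the
#' four preceding), normalized by the number of laps elapsed between the two
#' window centers (their amplitude-weighted mean laps, so a perfectly linear
#' drift of d cm/lap returns exactly d). Negative values are backward shifts.
#'
#' @param com_df data.frame `lap`, `com`, `peak`.
#' @param window averaging window in laps.
#' @return Shift in cm/lap; attribute `truncated` flags overlapping windows
#'   on short series. `NA` when fewer than 2 active laps.
#' @export
session_shift <- function(com_df, window = 5) {
  if (nrow(com_df) < 2) return(NA_real_)
  onset <- min(com_df$lap)
  last <- max(com_df$lap)
  sel_on <- com_df$lap >= onset & com_df$lap <= onset + window - 1L
  sel_last <- com_df$lap >= last - window + 1L & com_df$lap <= last
  com_onset <- weighted_com(com_df$com[sel_on], com_df$peak[sel_on])
  com_last <- weighted_com(com_df$com[sel_last], com_df$peak[sel_last])
  lap_onset <- weighted_com(com_df$lap[sel_on], com_df$peak[sel_on])
  lap_last <- weighted_com(com_df$lap[sel_last], com_df$peak[sel_last])
  if (lap_last == lap_onset) return(NA_real_)
  out <- (com_last - com_onset) / (lap_last - lap_onset)
  attr(out, "truncated") <- (last - onset + 1L) < 2L * window
  out
}

#' Lap-shuffle null for session shifts
#'
#' For each shuffle, permutes the lap labels of every field's COM series and
#' recomputes the session shift, yielding a null distribution of population
#' session shifts under exchangeability. The observed-vs-null contrast is
#' summarized with a bootstrapped mean difference.
#'
#' @param com_list list of per-field COM data.frames (`lap`, `com`, `peak`).
#' @param n_shuffles number of lap-label permutations.
#' @param seed RNG seed.
#' @param n_boot resamples for the estimation contrast.
#' @return A list: `observed` (per-field shifts), `null_mean` (per-shuffle
#'   population means), `null_all` (all null shifts), `estimation`
#'   ([bootstrap_mean_difference()] of observed minus null).
#' @export
lap_shuffle_null <- function(com_list, n_shuffles = 1000, seed = 1L,
                             n_boot = 2000) {
  set.seed(seed)
  observed <- vapply(com_list, session_shift, numeric(1))
  null_mean <- numeric(n_shuffles)
  null_all <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    shifts <- vapply(com_list, function(df) {
      df$lap <- sample(df$lap)
      session_shift(df[order(df$lap), , drop = FALSE])
    }, numeric(1))
    null_mean[s] <- mean(shifts, na.rm = TRUE)
    null_all[[s]] <- shifts
  }
  null_all <- unlist(null_all)
  est <- bootstrap_mean_difference(null_all[is.finite(null_all)],
                                   observed[is.finite(observed)],
                                   n_boot = n_boot,
                                   seed = derive_seed(seed, 1L))
  list(observed = observed, null_mean = null_mean, null_all = null_all,
       estimation = est)
}

#' Population COM shift curve relative to a reference lap
#'
#' For each field, the five-lap sliding amplitude-weighted COM; the lap-wise
#' shift is its difference from the value at the reference lap (12 by
#' default), which is therefore exactly 0 for every field. Only fields with
#' activity on the reference lap's window and an onset lap below
#' `max_onset_lap` are included. The curve reports the mean and SEM across
#' fields per lap (the number of contributing fields varies by lap), and an
#' OLS slope with F-test over all (field, lap) points.
#'
#' @param series_list list of per-field COM data.frames (`lap`, `com`,
#'   `peak`).
#' @param onsets per-field onset laps (same length).
#' @param config a [pf_config()] (reference lap, window, inclusion bound).
#' @param window override the sliding-window length (1 = unsmoothed).
#' @return An object of class `"pf_popcurve"`: `curve` (lap, mean, sem, n),
#'   `slope`, `p_value`, `points` (all field-lap shifts), `n_fields`.
#' @export
population_shift_curve <- function(series_list, onsets,
                                   config = pf_config(), window = NULL) {
  if (is.null(window)) window <- config$shift_window
  ref <- config$reference_lap
  pts <- vector("list", length(series_list))
  inc <- 0L
  for (i in seq_along(series_list)) {
    df <- series_list[[i]]
    if (is.na(onsets[i]) || onsets[i] >= config$max_onset_lap) next
    if (!(ref %in% df$lap)) next      # needs activity on the reference lap
    sl <- sliding_weighted_com(df, window)
    ref_val <- sl$com[sl$lap == ref]
    if (length(ref_val) != 1 || is.na(ref_val)) next
    inc <- inc + 1L
    pts[[i]] <- data.frame(field = i, lap = sl$lap, shift = sl$com - ref_val)
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0) {
    stop("no field satisfies the population-curve inclusion rule")
  }
  agg_m <- tapply(pts$shift, pts$lap, mean)
  agg_s <- tapply(pts$shift, pts$lap, function(v) {
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  agg_n <- tapply(pts$shift, pts$lap, length)
  fit <- ols_fit(pts$lap, pts$shift)
  structure(list(curve = data.frame(lap = as.integer(names(agg_m)),
                                    mean = as.numeric(agg_m),
                                    sem = as.numeric(agg_s),
                                    n = as.integer(agg_n)),
                 slope = fit$slope, p_value = fit$p, points = pts,
                 n_fields = inc, reference_lap = ref, window = window),
            class = "pf_popcurve")
}

#' @export
print.pf_popcurve <- function(x, ...) {
  cat(sprintf("pf_popcurve: %d fields, slope %.4f cm/lap (p = %.3g), reference lap %d\n",
              x$n_fields, x$slope, x$p_value, x$reference_lap))
  invisible(x)
}

#' @export
plot.pf_popcurve <- function(x, ...) {
  with(x$curve, {
    graphics::plot(lap, mean, type = "o", pch = 16,
                   ylim = range(c(mean - sem, mean + sem), na.rm = TRUE),
                   xlab = "lap", ylab = "COM shift vs reference lap (cm)",
                   ...)
    graphics::arrows(lap, mean - sem, lap, mean + sem, angle = 90, code = 3,
                     length = 0.02)
    graphics::abline(h = 0, lty = 3)
  })
  invisible(x)
}

#' Sample-size-matched resampled slope comparison
#'
#' Compares population shift slopes across conditions while controlling for
#' unequal field counts: the fields of each larger condition are resampled
#' without replacement `n_resamples` times at a matched size (the smaller
#' condition's count for two conditions; 80\% of the smallest count when
#' more than two), refitting the pooled (field, lap) regression each time.
#'
#' @param points_list named list; each element the `points` data.frame of a
#'   [population_shift_curve()] (columns `field`, `lap`, `shift`).
#' @param n_resamples resampling iterations (< 100 warns).
#' @param seed RNG seed.
#' @return A list: `slopes` (matrix n_resamples x condition; conditions at
#'   the matched size are resampled, a condition already at the matched size
#'   keeps its full-data slope in every row), `full_slopes`, `n_matched`,
#'   and `overlap` (logical matrix: do the resampled slope ranges of two
#'   conditions overlap).
#' @export
resampled_slope_comparison <- function(points_list, n_resamples = 1000,
                                       seed = 1L) {
  if (n_resamples < 100) warning("n_resamples < 100 is unstable")
  set.seed(seed)
  sizes <- vapply(points_list, function(p) length(unique(p$field)), integer(1))
  n_matched <- if (length(points_list) > 2) {
    max(2L, floor(0.8 * min(sizes)))
  } else min(sizes)
  full <- vapply(points_list,
                 function(p) ols_fit(p$lap, p$shift)$slope, numeric(1))
  slopes <- matrix(NA_real_, n_resamples, length(points_list),
                   dimnames = list(NULL, names(points_list)))
  for (j in seq_along(points_list)) {
    p <- points_list[[j]]
    ids <- unique(p$field)
    if (length(ids) <= n_matched) {
      slopes[, j] <- full[j]
      next
    }
    for (r in seq_len(n_resamples)) {
      sub <- p[p$field %in% sample(ids, n_matched), , drop = FALSE]
      slopes[r, j] <- ols_fit(sub$lap, sub$shift)$slope
    }
  }
  k <- length(points_list)
  overlap <- matrix(NA, k, k, dimnames = list(names(points_list),
                                              names(points_list)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    overlap[a, b] <- min(slopes[, a]) <= max(slopes[, b]) &&
      min(slopes[, b]) <= max(slopes[, a])
  }
  list(slopes = slopes, full_slopes = full, n_matched = n_matched,
       overlap = overlap)
}

#' Across-day offline shift and reset of matched fields
#'
#' For each field matched across days, the offline shift is the COM on the
#' first active lap of day 2 minus the COM on the last active lap of day 1.
#' For the reset analysis, the day-2 starting position is also compared with
#' the field's early day-1 position (weighted COM over the first five active
#' laps): after significant backward shifting on day 1, stable fields tend
#' to restart closer to where they began.
#'
#' @param series1,series2 lists of per-field COM data.frames for day 1 and
#'   day 2, index-matched; entries with no activity on a day are skipped and
#'   counted.
#' @return A list: `table` (per-field `com_last_d1`, `com_first_d2`,
#'   `offline_shift_cm`, `com_early_d1`, `reset_cm` = day-2 start minus
#'   day-1 early position), `signrank_p` (two-sided test of the offline
#'   shifts against 0), `n_unmatched`.
#' @export
across_day_shift <- function(series1, series2) {
  stopifnot(length(series1) == length(series2))
  rows <- list()
  unmatched <- 0L
  for (i in seq_along(series1)) {
    d1 <- series1[[i]]; d2 <- series2[[i]]
    if (is.null(d1) || is.null(d2) || nrow(d1) == 0 || nrow(d2) == 0) {
      unmatched <- unmatched + 1L
      next
    }
    com_last_d1 <- d1$com[which.max(d1$lap)]
    com_first_d2 <- d2$com[which.min(d2$lap)]
    early <- head(d1[order(d1$lap), ], 5)
    rows[[length(rows) + 1L]] <- data.frame(
      field = i, com_last_d1 = com_last_d1, com_first_d2 = com_first_d2,
      offline_shift_cm = com_first_d2 - com_last_d1,
      com_early_d1 = weighted_com(early$com, early$peak),
      reset_cm = com_first_d2 - weighted_com(early$com, early$peak))
  }
  tab <- do.call(rbind, rows)
  p <- if (!is.null(tab) && nrow(tab) >= 2 &&
           any(tab$offline_shift_cm != 0)) {
    suppressWarnings(wilcox.test(tab$offline_shift_cm)$p.value)
  } else NA_real_
  list(table = tab, signrank_p = p, n_unmatched = unmatched)
}
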