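#' Segment laps from a raw position trace
#'
#' A new lap starts at each large negative position discontinuity (the
#' teleport back to the track start). Pause samples at the end of the track
#' are assigned to the tail of the completed lap.
#'
#' @param position position per sample (cm).
#' @param time timestamps (s), strictly increasing.
#' @param min_drop minimum negative jump (cm) treated as a teleport; defaults
#'   to half the position range.
#' @return A data.frame with one row per lap: `lap`, `start_idx`, `end_idx`
#'   (inclusive sample indices), `t_start`, `t_end`.
#' @export
segment_laps <- function(position, time, min_drop = NULL) {
  stopifnot(length(position) == length(time), all(diff(time) > 0))
  if (is.null(min_drop)) min_drop <- diff(range(position)) / 2
  d <- diff(position)
  resets <- which(d < -min_drop)          # lap ends at index resets[i]
  if (length(resets) == 0) {
    warning("no position resets found; treating the whole trace as one lap")
    return(data.frame(lap = 1L, start_idx = 1L, end_idx = length(position),
                      t_start = time[1], t_end = time[length(time)]))
  }
  starts <- c(1L, resets + 1L)
  ends <- c(resets, length(position))
  data.frame(lap = seq_along(starts), start_idx = starts, end_idx = ends,
             t_start = time[starts], t_end = time[ends])
}

#' Per-sample lap index from segmented laps
#' @param laps output of [segment_laps()].
#' @param n total number of samples.
#' @return Integer vector of lap indices.
#' @export
lap_index_from_segments <- function(laps, n) {
  idx <- integer(n)
  for (i in seq_len(nrow(laps))) idx[laps$start_idx[i]:laps$end_idx[i]] <- laps$lap[i]
  idx
}

#' Instantaneous velocity from position
#'
#' Centered finite differences of position over time, then a boxcar smooth.
#' Teleport discontinuities are excluded from the difference (set to the
#' neighboring within-lap estimate).
#'
#' @param position,time per-sample position (cm) and timestamps (s).
#' @param smooth_s boxcar width (s); 0 disables smoothing.
#' @param track_length_cm used to recognize teleport jumps.
#' @return Velocity per sample (cm/s).
#' @export
compute_velocity <- function(position, time, smooth_s = 0.5,
                             track_length_cm = max(position)) {
  n <- length(position)
  stopifnot(n >= 3)
  d <- diff(position)
  d[d < -track_length_cm / 2] <- NA  # teleports
  dt <- diff(time)
  v_mid <- d / dt
  ## centered: average of backward and forward one-sided estimates
  v <- c(v_mid[1], (v_mid[-1] + v_mid[-(n - 1)]) / 2, v_mid[n - 1])
  ## fill teleport NAs with nearest finite value
  if (anyNA(v)) {
    ok <- which(!is.na(v))
    v <- approx(ok, v[ok], xout = seq_len(n), rule = 2)$y
  }
  if (smooth_s > 0) {
    w <- max(1L, round(smooth_s / mean(dt)))
    if (w > 1) {
      k <- rep(1 / w, w)
      v <- as.numeric(stats::filter(v, k, sides = 2))
      v[is.na(v)] <- 0
      ## edges: partial means
      half <- floor(w / 2)
      for (i in seq_len(min(half, n))) {
        v[i] <- mean(v_mid[seq_len(min(i + half, n - 1))], na.rm = TRUE)
        v[n + 1 - i] <- mean(v_mid[seq(max(1, n - i - half), n - 1)], na.rm = TRUE)
      }
    }
  }
  v
}

#' Locomotion mask
#'
#' TRUE for samples moving forward at or above the immobility threshold.
#' Samples strictly slower than `threshold` (default 0.2 cm/s) or moving
#' backward are masked out of all spatial binning.
#'
#' @param velocity velocity per sample (cm/s).
#' @param threshold immobility threshold (cm/s); the boundary value is kept.
#' @return Logical vector.
#' @export
locomotion_mask <- function(velocity, threshold = 0.2) {
  velocity >= threshold
}

#' Mean lap velocity and normalized variants
#'
#' Lap velocity is the track length divided by the time taken to traverse the
#' lap. By default the end-of-lap pause is excluded from the duration (the
#' traversal time); set `include_pause = TRUE` to include it.
#'
#' @param behavior a `"pf_behavior"` object (or any list with `position_cm`,
#'   `time_s`, `is_pause`, `track_length_cm`).
#' @param include_pause include the end-of-track pause in lap duration.
#' @return A data.frame: `lap`, `t_start`, `t_end`, `duration_s`, `v_cm_s`.
#' @export
lap_velocity <- function(behavior, include_pause = FALSE) {
  laps <- segment_laps(behavior$position_cm, behavior$time_s)
  dt <- 1 / behavior$frame_rate_hz
  v <- numeric(nrow(laps))
  dur <- numeric(nrow(laps))
  for (i in seq_len(nrow(laps))) {
    idx <- laps$start_idx[i]:laps$end_idx[i]
    if (!include_pause && !is.null(behavior$is_pause)) {
      idx <- idx[!behavior$is_pause[idx]]
    }
    dur[i] <- length(idx) * dt
    v[i] <- behavior$track_length_cm / dur[i]
  }
  data.frame(lap = laps$lap, t_start = laps$t_start, t_end = laps$t_end,
             duration_s = dur, v_cm_s = v)
}

#' Normalize lap velocities to a familiar-environment reference
#'
#' Divides each lap's mean velocity by the mean velocity of the first three
#' laps of the reference (familiar) session.
#'
#' @param v_lap vector of lap velocities (cm/s).
#' @param v_reference lap velocities of the reference session; needs >= 3 laps.
#' @return Normalized velocities (unitless).
#' @export
normalize_lap_velocity <- function(v_lap, v_reference = v_lap) {
  if (length(v_reference) < 3) {
    stop("normalization needs at least 3 reference laps")
  }
  v_lap / mean(v_reference[1:3])
}
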