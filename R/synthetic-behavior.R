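#' Behavior generator configuration
#'
#' Parameters of the virtual linear-track paradigm emulated by the generator:
#' unidirectional traversals of a 3 m track at ~11 Hz sampling, each lap ending
#' with a 1.5 s pause before an instantaneous teleport back to the start.
#'
#' @param track_length_cm track length (cm).
#' @param n_laps number of laps.
#' @param mean_speed_cm_s mean running speed across laps (cm/s).
#' @param speed_cv coefficient of variation of per-lap speed (lognormal).
#' @param pause_s end-of-lap pause before teleport (s).
#' @param frame_rate_hz effective per-plane sampling rate (Hz).
#' @return A list of class `"pf_behavior_config"`.
#' @export
behavior_config <- function(track_length_cm = 300, n_laps = 30,
                            mean_speed_cm_s = 25, speed_cv = 0.15,
                            pause_s = 1.5, frame_rate_hz = 10.7) {
  stopifnot(track_length_cm > 0, n_laps >= 1, frame_rate_hz > 0,
            pause_s >= 0, speed_cv >= 0)
  if (mean_speed_cm_s <= 0) stop("mean_speed_cm_s must be positive")
  structure(list(track_length_cm = track_length_cm, n_laps = n_laps,
                 mean_speed_cm_s = mean_speed_cm_s, speed_cv = speed_cv,
                 pause_s = pause_s, frame_rate_hz = frame_rate_hz),
            class = "pf_behavior_config")
}

#' Generate a synthetic behavior trace
#'
#' Simulates unidirectional running: within each lap, position increases
#' linearly from 0 to the track length at a per-lap speed drawn from a
#' lognormal distribution with the configured mean and CV, followed by a pause
#' at the end of the track and an instantaneous teleport back to 0.
#'
#' @param cfg a [behavior_config()].
#' @param seed RNG seed; identical `(cfg, seed)` give identical traces.
#' @return An object of class `"pf_behavior"`: a list with per-sample
#'   `time_s`, `position_cm`, `velocity_cm_s`, `lap_index` (1-based; pause
#'   samples carry the completed lap's index), logical `is_pause`, and the
#'   scalars `track_length_cm`, `frame_rate_hz`, `n_laps`.
#' @export
generate_behavior <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "pf_behavior_config"))
  set.seed(seed)
  dt <- 1 / cfg$frame_rate_hz
  if (cfg$speed_cv > 0) {
    s2 <- log(1 + cfg$speed_cv^2)
    speeds <- rlnorm(cfg$n_laps, log(cfg$mean_speed_cm_s) - s2 / 2, sqrt(s2))
  } else {
    speeds <- rep(cfg$mean_speed_cm_s, cfg$n_laps)
  }
  n_pause <- round(cfg$pause_s / dt)
  pos <- vector("list", cfg$n_laps)
  lap <- vector("list", cfg$n_laps)
  vel <- vector("list", cfg$n_laps)
  pause <- vector("list", cfg$n_laps)
  for (l in seq_len(cfg$n_laps)) {
    step <- speeds[l] * dt
    p_run <- seq(0, cfg$track_length_cm - 1e-9, by = step)
    p <- c(p_run, rep(cfg$track_length_cm, n_pause))
    pos[[l]] <- p
    lap[[l]] <- rep(l, length(p))
    vel[[l]] <- c(rep(speeds[l], length(p_run)), rep(0, n_pause))
    pause[[l]] <- c(rep(FALSE, length(p_run)), rep(TRUE, n_pause))
  }
  position <- unlist(pos)
  n <- length(position)
  structure(list(time_s = (seq_len(n) - 1) * dt,
                 position_cm = position,
                 velocity_cm_s = unlist(vel),
                 lap_index = unlist(lap),
                 is_pause = unlist(pause),
                 track_length_cm = cfg$track_length_cm,
                 frame_rate_hz = cfg$frame_rate_hz,
                 n_laps = cfg$n_laps,
                 lap_speeds_cm_s = speeds),
            class = "pf_behavior")
}

#' @export
print.pf_behavior <- function(x, ...) {
  cat(sprintf("pf_behavior: %d laps on %g cm track, %d samples at %g Hz (%.1f s)\n",
              x$n_laps, x$track_length_cm, length(x$time_s), x$frame_rate_hz,
              max(x$time_s)))
  invisible(x)
}
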