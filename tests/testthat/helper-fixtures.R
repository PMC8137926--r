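# shared fixtures, built in code at test time

quick_behavior <- function(n_laps = 30, seed = 1, speed = 25, cv = 0.15,
                           pause = 1.5) {
  generate_behavior(behavior_config(n_laps = n_laps, mean_speed_cm_s = speed,
                                    speed_cv = cv, pause_s = pause),
                    seed = seed)
}

# one-field cell with sensible defaults
quick_cell <- function(center = 150, width = 60, amp = 1, onset = 1,
                       drift = 0, ...) {
  ground_truth_cell(center, width, amp, onset, drift_cm_per_lap = drift, ...)
}

# lap-by-bin matrix straight from a raw trace (no detection), for tests
# where the synthetic trace is already baseline-free
raw_matrix <- function(trace, behavior, n_bins = 50) {
  lap_bin_matrix(trace, behavior, n_bins = n_bins)
}

# a minimal hand-built lap-bin matrix with attributes set
toy_matrix <- function(values, track_length = 300) {
  n_bins <- ncol(values)
  bw <- track_length / n_bins
  attr(values, "bin_centers_cm") <- (seq_len(n_bins) - 0.5) * bw
  attr(values, "bin_width_cm") <- bw
  values
}
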