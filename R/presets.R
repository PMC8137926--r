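## Generator presets emulating the two hippocampal subfield phenotypes:
## "ca1_day1"  -- instant-rich (30% lap-1 onsets, geometric tail), fast
##                backward drift (-0.5 cm/lap), lower across-day stability
## "ca3_day1"  -- delayed (9% lap-1 onsets, uniform remainder), slow drift
##                (-0.1 cm/lap), higher across-day stability
## "paired_days" -- instant-rich population recorded on two days

preset_params <- function(name) {
  switch(name,
    ca1_day1 = list(p_instant = 0.30, onset_mode = "geometric",
                    onset_decay = 0.2, max_onset = 18L,
                    drift_mean = -0.5, drift_sd = 0.1,
                    stable_fraction = 0.5, day2_p_instant = 0.3),
    ca3_day1 = list(p_instant = 0.09, onset_mode = "uniform",
                    onset_decay = NA, max_onset = 18L,
                    drift_mean = -0.1, drift_sd = 0.05,
                    stable_fraction = 0.8, day2_p_instant = 0.6),
    stop("unknown preset '", name,
         "'; available: ca1_day1, ca3_day1, paired_days")
  )
}

#' Draw a preset population of ground-truth cells
#'
#' Samples single-field cells with uniform centers, widths of 40--80 cm,
#' lognormal amplitudes around 0.8 \eqn{\Delta}F/F, lap-to-lap reliability
#' 0.9, a low out-of-field event rate, and the preset's onset-lap
#' distribution, per-lap drift, and across-day fate mix.
#'
#' @param name `"ca1_day1"` or `"ca3_day1"`.
#' @param n_cells number of cells.
#' @param track_length_cm track length (cm).
#' @param seed RNG seed.
#' @param drift_mean override the preset drift mean (cm/lap).
#' @param reliability per-lap transient probability.
#' @return A list of [ground_truth_cell()]s.
#' @export
preset_truth <- function(name, n_cells = 90, track_length_cm = 300,
                         seed = 1L, drift_mean = NULL, reliability = 0.9) {
  p <- preset_params(name)
  if (!is.null(drift_mean)) p$drift_mean <- drift_mean
  set.seed(seed)
  onsets <- vapply(seq_len(n_cells), function(i) {
    if (runif(1) < p$p_instant) return(1L)
    if (p$onset_mode == "uniform") {
      sample(2:p$max_onset, 1)
    } else {
      min(2L + stats::rgeom(1, p$onset_decay), p$max_onset)
    }
  }, integer(1))
  fates <- ifelse(runif(n_cells) < p$stable_fraction, "stable", "remap")
  lapply(seq_len(n_cells), function(i) {
    ground_truth_cell(
      centers_cm = runif(1, 0.06, 0.94) * track_length_cm,
      widths_cm = runif(1, 40, 80),
      amplitudes_dff = max(0.3, rlnorm(1, log(0.8), 0.25)),
      onset_laps = onsets[i],
      drift_cm_per_lap = rnorm(1, p$drift_mean, p$drift_sd),
      reliability = reliability,
      oof_rate_hz = 0.01,
      day2_fate = fates[i],
      track_length_cm = track_length_cm)
  })
}

#' Simulate a preset session
#'
#' One call from preset name to a ready synthetic session (or pair of daily
#' sessions for `"paired_days"`).
#'
#' @param name `"ca1_day1"`, `"ca3_day1"` or `"paired_days"`.
#' @param n_cells number of cells.
#' @param n_laps laps per session.
#' @param seed master seed.
#' @param noise_sigma additive noise sd (\eqn{\Delta}F/F).
#' @param ... passed to [preset_truth()].
#' @return A `"pf_session"`, or for `"paired_days"` a list `day1`/`day2`.
#' @export
simulate_preset <- function(name, n_cells = 90, n_laps = 40, seed = 1L,
                            noise_sigma = 0.05, ...) {
  if (name == "paired_days") {
    cells <- preset_truth("ca1_day1", n_cells, seed = derive_seed(seed, 7L), ...)
    cfg <- behavior_config(n_laps = n_laps)
    return(synthesize_paired_days(cfg, cells, seed = seed,
                                  noise_sigma = noise_sigma,
                                  day2_p_instant = preset_params("ca1_day1")$day2_p_instant))
  }
  p <- preset_params(name)
  cells <- preset_truth(name, n_cells, seed = derive_seed(seed, 7L), ...)
  cfg <- behavior_config(n_laps = n_laps)
  synthesize_session(cfg, cells, noise_sigma, seed = seed)
}

#' Simulate preset paired-day sessions for a named subfield phenotype
#'
#' Like [simulate_preset()] but always produces the two-day design, using the
#' named preset's stable fraction and day-2 re-emergence distribution.
#'
#' @inheritParams simulate_preset
#' @return A list `day1`/`day2` of `"pf_session"` objects.
#' @export
simulate_preset_days <- function(name, n_cells = 90, n_laps = 40, seed = 1L,
                                 noise_sigma = 0.05, ...) {
  p <- preset_params(name)
  cells <- preset_truth(name, n_cells, seed = derive_seed(seed, 7L), ...)
  cfg <- behavior_config(n_laps = n_laps)
  synthesize_paired_days(cfg, cells, seed = seed, noise_sigma = noise_sigma,
                         day2_p_instant = p$day2_p_instant)
}
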