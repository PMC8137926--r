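#' Analysis configuration
#'
#' All thresholds of the pipeline in one list, each with its standard default:
#' 50 spatial bins of 6 cm on a 300 cm track, the 2\eqn{\sigma}/0.5\eqn{\sigma}
#' transient rule with a <1\% false-positive amplitude/duration filter, the
#' four place-field criteria (width 20--150 cm, peak > 0.1 \eqn{\Delta}F/F,
#' in/out ratio > 3, activity on >= 15 laps) with a 1000-iteration bootstrap
#' at p < 0.05, the 3-of-6 onset-lap rule, and the population-shift reference
#' lap 12 with a 5-lap sliding window.
#'
#' @param track_length_cm track length in cm.
#' @param n_bins number of spatial bins for field analysis.
#' @param n_fine_bins number of fine bins for the decoder grid.
#' @param velocity_threshold_cm_s immobility threshold; samples strictly slower
#'   are excluded from spatial binning.
#' @param velocity_smooth_s boxcar width for velocity smoothing (s).
#' @param baseline_window_s half-width of the rolling-percentile baseline
#'   window (s).
#' @param baseline_percentile percentile subtracted by the baseline correction.
#' @param onset_sigma,offset_sigma transient start/end thresholds in
#'   \eqn{\sigma} units.
#' @param fpr_amplitudes_sigma,fpr_durations_s grid of minimum amplitudes
#'   (\eqn{\sigma}) and durations (s) for the false-positive-rate filter.
#' @param fpr_max_ratio maximum negative/positive event ratio for a grid class
#'   to be accepted.
#' @param pf_threshold_frac candidate threshold as a fraction of peak minus
#'   baseline.
#' @param pf_baseline_bins number of lowest bins averaged into the baseline.
#' @param pf_width_min_cm,pf_width_max_cm field width bounds (exclusive).
#' @param pf_min_peak_dff minimum in-field peak of the mean map.
#' @param pf_min_ratio minimum in-field/out-field mean ratio.
#' @param pf_min_laps minimum number of laps with in-field transients.
#' @param n_boot bootstrap iterations for field significance.
#' @param p_threshold significance level for the bootstrap p-value.
#' @param onset_rule laps (out of `onset_window`) with in-field transients
#'   required at the onset lap.
#' @param onset_window onset scan window length in laps.
#' @param shift_min_laps minimum active laps for a per-field shift regression.
#' @param reference_lap reference lap of the population shift curve.
#' @param shift_window sliding-window length (laps) for weighted COMs.
#' @param max_onset_lap inclusion bound: fields with onset lap below this value
#'   enter the population curve.
#' @param stability_laps laps per window for across-day correlations.
#' @param stable_r spatial correlation above which a field counts as stable.
#' @param decoder_var_floor variance floor of the Gaussian naive Bayes decoder
#'   (\eqn{\Delta}F/F\eqn{^2}).
#' @param n_boot_estimation resamples for bootstrapped mean differences.
#' @return A list of class `"pf_config"`.
#' @export
pf_config <- function(track_length_cm = 300,
                      n_bins = 50,
                      n_fine_bins = 100,
                      velocity_threshold_cm_s = 0.2,
                      velocity_smooth_s = 0.5,
                      baseline_window_s = 5,
                      baseline_percentile = 0.08,
                      onset_sigma = 2,
                      offset_sigma = 0.5,
                      fpr_amplitudes_sigma = c(2, 2.5, 3, 3.5, 4),
                      fpr_durations_s = c(0.2, 0.4, 0.6, 0.8, 1),
                      fpr_max_ratio = 0.01,
                      pf_threshold_frac = 0.15,
                      pf_baseline_bins = 12,
                      pf_width_min_cm = 20,
                      pf_width_max_cm = 150,
                      pf_min_peak_dff = 0.1,
                      pf_min_ratio = 3,
                      pf_min_laps = 15,
                      n_boot = 1000,
                      p_threshold = 0.05,
                      onset_rule = 3,
                      onset_window = 6,
                      shift_min_laps = 5,
                      reference_lap = 12,
                      shift_window = 5,
                      max_onset_lap = 20,
                      stability_laps = 10,
                      stable_r = 0.5,
                      decoder_var_floor = 1e-4,
                      n_boot_estimation = 5000) {
  cfg <- as.list(environment())
  stopifnot(track_length_cm > 0, n_bins >= 1, n_fine_bins >= n_bins)
  cfg$bin_width_cm <- track_length_cm / n_bins
  cfg$fine_bin_width_cm <- track_length_cm / n_fine_bins
  class(cfg) <- "pf_config"
  cfg
}

#' @export
print.pf_config <- function(x, ...) {
  cat("pfdyn analysis configuration\n")
  cat(sprintf("  track %g cm, %d bins of %g cm (decoder: %d bins of %g cm)\n",
              x$track_length_cm, x$n_bins, x$bin_width_cm,
              x$n_fine_bins, x$fine_bin_width_cm))
  cat(sprintf("  transients: %g sigma onset / %g sigma offset, FPR < %g\n",
              x$onset_sigma, x$offset_sigma, x$fpr_max_ratio))
  cat(sprintf("  fields: width (%g, %g) cm, peak > %g, ratio > %g, >= %d laps, p < %g (%d boot)\n",
              x$pf_width_min_cm, x$pf_width_max_cm, x$pf_min_peak_dff,
              x$pf_min_ratio, x$pf_min_laps, x$p_threshold, x$n_boot))
  cat(sprintf("  onset: %d of %d laps; shift reference lap %d, window %d\n",
              x$onset_rule, x$onset_window, x$reference_lap, x$shift_window))
  invisible(x)
}

## deterministic child seed derivation (Lehmer step), keeps seeds < 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 11 * i) %% 2147483629)
}
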