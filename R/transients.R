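#' Rolling-percentile baseline correction
#'
#' Removes slow drift from a \eqn{\Delta}F/F trace by subtracting, at each
#' sample, the 8th percentile of the fluorescence distribution in a +/- 5 s
#' window around it (truncated at the trace edges). The percentile is
#' evaluated on a strided grid and linearly interpolated between grid points,
#' which is indistinguishable from the dense computation at these window
#' sizes.
#'
#' @param dff raw \eqn{\Delta}F/F per frame.
#' @param frame_rate sampling rate (Hz).
#' @param window_s window half-width (s).
#' @param prob percentile subtracted (0.08 = 8th percentile).
#' @param stride grid spacing in samples for the percentile evaluation; 1
#'   computes it at every sample.
#' @return Baseline-subtracted trace, same length as `dff`.
#' @export
correct_baseline <- function(dff, frame_rate, window_s = 5, prob = 0.08,
                             stride = 5L) {
  n <- length(dff)
  if (all(is.na(dff))) stop("all-NaN trace")
  if (n < 10 * frame_rate) stop("trace shorter than 10 s")
  half <- max(1L, round(window_s * frame_rate))
  grid <- unique(c(seq(1L, n, by = as.integer(stride)), n))
  q <- vapply(grid, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    quantile(dff[lo:hi], prob, na.rm = TRUE, names = FALSE)
  }, numeric(1))
  baseline <- if (length(grid) == n) q else approx(grid, q, xout = seq_len(n))$y
  dff - baseline
}

#' Estimate the baseline level and noise sigma of a corrected trace
#'
#' The drift-corrected trace still sits at a small positive offset (the
#' subtracted percentile is below the noise median), and transients must not
#' inflate the noise estimate, so both quantities are estimated from the
#' samples that do not contain large transients: the median and
#' 1.4826 x the median absolute deviation, iterated with exclusion of
#' provisional >2 sigma excursions. Sigma is floored at `floor` so
#' near-noiseless traces can still pass through the threshold detector.
#'
#' @param dff_corrected drift-corrected trace.
#' @param n_iter refinement iterations.
#' @param floor minimum returned sigma (\eqn{\Delta}F/F).
#' @return A list: `center` (baseline level), `sigma`.
#' @export
estimate_noise <- function(dff_corrected, n_iter = 3, floor = 1e-3) {
  x <- dff_corrected[is.finite(dff_corrected)]
  ctr <- median(x)
  s <- max(mad(x, center = ctr), floor)
  for (i in seq_len(n_iter)) {
    keep <- abs(x - ctr) <= 2 * s
    if (sum(keep) > 10) {
      ctr <- median(x[keep])
      s <- max(mad(x[keep], center = ctr), floor)
    }
  }
  list(center = ctr, sigma = s)
}

#' Noise sigma of a baseline-centered trace
#'
#' @param dff_corrected baseline-corrected, baseline-centered trace.
#' @param n_iter,floor see [estimate_noise()].
#' @return Estimated noise sigma.
#' @export
estimate_sigma <- function(dff_corrected, n_iter = 3, floor = 1e-3) {
  estimate_noise(dff_corrected, n_iter, floor)$sigma
}

## threshold-crossing events on one sign: start at >= on_thr, end when the
## trace returns below off_thr (or trace end). Returns onset/offset frames,
## peak and half-peak duration.
find_events_one_sign <- function(x, on_thr, off_thr, frame_rate) {
  above <- x >= on_thr
  if (!any(above)) {
    return(data.frame(onset = integer(0), offset = integer(0),
                      peak = numeric(0), duration_s = numeric(0)))
  }
  n <- length(x)
  below <- x < off_thr
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && !below[j + 1L]) j <- j + 1L
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  peak <- vapply(seq_along(starts),
                 function(k) max(x[starts[k]:ends[k]]), numeric(1))
  dur <- vapply(seq_along(starts), function(k) {
    seg <- x[starts[k]:ends[k]]
    sum(seg >= peak[k] / 2) / frame_rate
  }, numeric(1))
  data.frame(onset = starts, offset = ends, peak = peak, duration_s = dur)
}

#' False-positive-rate acceptance table for transient classes
#'
#' For a grid of minimum-amplitude (in sigma units) x minimum-duration
#' classes, computes the ratio of negative- to positive-going events falling
#' in each class on the same trace. Classes with ratio below `max_ratio`
#' (default 1\%) are accepted; acceptance is made monotone so that any class
#' stricter than an accepted class is accepted too.
#'
#' @param positive,negative event tables from [find_events_one_sign()]-style
#'   detection on the trace and its sign-flipped copy.
#' @param sigma noise sigma of the trace.
#' @param amplitudes_sigma,durations_s grid of class thresholds.
#' @param max_ratio acceptance threshold on n_neg/n_pos.
#' @return A data.frame with one row per grid class: `min_amp_sigma`,
#'   `min_dur_s`, `n_pos`, `n_neg`, `ratio`, `accepted`.
#' @export
calibrate_fpr <- function(positive, negative, sigma,
                          amplitudes_sigma = c(2, 2.5, 3, 3.5, 4),
                          durations_s = c(0.2, 0.4, 0.6, 0.8, 1),
                          max_ratio = 0.01) {
  grid <- expand.grid(min_amp_sigma = amplitudes_sigma,
                      min_dur_s = durations_s)
  count_in <- function(ev, a, d) {
    sum(ev$peak >= a * sigma & ev$duration_s >= d)
  }
  grid$n_pos <- mapply(count_in, a = grid$min_amp_sigma, d = grid$min_dur_s,
                       MoreArgs = list(ev = positive))
  grid$n_neg <- mapply(count_in, a = grid$min_amp_sigma, d = grid$min_dur_s,
                       MoreArgs = list(ev = negative))
  grid$ratio <- ifelse(grid$n_pos > 0, grid$n_neg / grid$n_pos, NA_real_)
  grid$accepted <- grid$n_pos > 0 & (grid$n_neg / grid$n_pos) < max_ratio
  if (nrow(positive) == 0) warning("no positive events; empty acceptance table")
  ## monotone closure: stricter classes inherit acceptance
  for (k in which(grid$accepted)) {
    stricter <- grid$min_amp_sigma >= grid$min_amp_sigma[k] &
      grid$min_dur_s >= grid$min_dur_s[k] & grid$n_pos > 0
    grid$accepted[stricter] <- TRUE
  }
  grid
}

#' Detect significant calcium transients
#'
#' Full detection chain: baseline correction (rolling 8th percentile), noise
#' sigma estimation, threshold events (start at 2\eqn{\sigma}, end on return
#' within 0.5\eqn{\sigma} of baseline) on both the trace and its sign-flipped
#' copy, then the amplitude/duration false-positive filter: only positive
#' events falling in a grid class whose negative/positive ratio is below 1\%
#' are kept. The returned significant-transient-only trace is zero outside
#' the surviving events and is the input to all spatial binning.
#'
#' @param dff raw \eqn{\Delta}F/F trace.
#' @param frame_rate sampling rate (Hz).
#' @param config a [pf_config()].
#' @param corrected set TRUE if `dff` is already baseline-corrected.
#' @return An object of class `"pf_transients"`: `dff_corrected`, `sigma`,
#'   `events` (accepted positive events: onset/offset frame, peak, half-peak
#'   duration), `events_all`, `events_negative`, `fpr_table`, `sig_trace`.
#' @export
detect_transients <- function(dff, frame_rate, config = pf_config(),
                              corrected = FALSE) {
  x <- if (corrected) dff else {
    correct_baseline(dff, frame_rate, config$baseline_window_s,
                     config$baseline_percentile)
  }
  noise <- estimate_noise(x)
  x <- x - noise$center   # re-center on the corrected baseline
  sigma <- noise$sigma
  if (sigma <= 0) stop("sigma estimation failed")
  pos <- find_events_one_sign(x, config$onset_sigma * sigma,
                              config$offset_sigma * sigma, frame_rate)
  neg <- find_events_one_sign(-x, config$onset_sigma * sigma,
                              config$offset_sigma * sigma, frame_rate)
  fpr <- suppressWarnings(
    calibrate_fpr(pos, neg, sigma, config$fpr_amplitudes_sigma,
                  config$fpr_durations_s, config$fpr_max_ratio))
  acc <- fpr[fpr$accepted, , drop = FALSE]
  keep <- rep(FALSE, nrow(pos))
  for (k in seq_len(nrow(acc))) {
    keep <- keep | (pos$peak >= acc$min_amp_sigma[k] * sigma &
                      pos$duration_s >= acc$min_dur_s[k])
  }
  events <- pos[keep, , drop = FALSE]
  sig <- numeric(length(x))
  for (k in seq_len(nrow(events))) {
    idx <- events$onset[k]:events$offset[k]
    sig[idx] <- x[idx]
  }
  structure(list(dff_corrected = x, sigma = sigma, events = events,
                 events_all = pos, events_negative = neg, fpr_table = fpr,
                 sig_trace = sig, frame_rate = frame_rate),
            class = "pf_transients")
}

#' @export
print.pf_transients <- function(x, ...) {
  cat(sprintf("pf_transients: %d significant / %d candidate events, sigma = %.4f\n",
              nrow(x$events), nrow(x$events_all), x$sigma))
  invisible(x)
}

#' Summary statistics of significant transients
#'
#' @param events accepted event table (from [detect_transients()]).
#' @param trace_duration_s total trace duration (s).
#' @return A list: `peaks` (\eqn{\Delta}F/F), `durations_s` (at half peak),
#'   `frequency_hz` (events per second).
#' @export
transient_stats <- function(events, trace_duration_s) {
  list(peaks = events$peak, durations_s = events$duration_s,
       frequency_hz = nrow(events) / trace_duration_s)
}
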