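#' Ground-truth parameters for one synthetic place cell
#'
#' Describes the fields a simulated neuron expresses: center, width and peak
#' amplitude per field, the lap each field first appears, a signed per-lap
#' drift of the field center (negative = backward, against the running
#' direction), the asymmetry of the spatial envelope, the probability of
#' emitting a transient on a post-onset lap, an out-of-field transient rate,
#' and the cell's fate on a second exposure a day later.
#'
#' @param centers_cm field centers (cm), one per field.
#' @param widths_cm field widths (cm); the Gaussian envelope sd is width/4.
#' @param amplitudes_dff peak \eqn{\Delta}F/F per field.
#' @param onset_laps first lap each field is expressed (1-based).
#' @param drift_cm_per_lap signed per-lap center drift.
#' @param skew_param skew-normal shape of the spatial envelope (0 =
#'   symmetric Gaussian).
#' @param reliability probability a field emits a transient on a post-onset
#'   lap.
#' @param oof_rate_hz Poisson rate of out-of-field transients (events/s).
#' @param day2_fate one of `"stable"`, `"remap"`, `"silent"`.
#' @param track_length_cm used to validate centers.
#' @return A list of class `"pf_truth_cell"`.
#' @export
ground_truth_cell <- function(centers_cm, widths_cm, amplitudes_dff,
                              onset_laps, drift_cm_per_lap = 0,
                              skew_param = 0, reliability = 1,
                              oof_rate_hz = 0, day2_fate = "stable",
                              track_length_cm = 300) {
  k <- length(centers_cm)
  stopifnot(length(widths_cm) == k, length(amplitudes_dff) == k,
            length(onset_laps) == k,
            all(centers_cm >= 0), all(centers_cm < track_length_cm),
            all(widths_cm > 0), all(onset_laps >= 1),
            reliability >= 0, reliability <= 1, oof_rate_hz >= 0)
  day2_fate <- match.arg(day2_fate, c("stable", "remap", "silent"))
  drift_cm_per_lap <- rep_len(drift_cm_per_lap, k)
  structure(list(centers_cm = centers_cm, widths_cm = widths_cm,
                 amplitudes_dff = amplitudes_dff, onset_laps = onset_laps,
                 drift_cm_per_lap = drift_cm_per_lap,
                 skew_param = skew_param, reliability = reliability,
                 oof_rate_hz = oof_rate_hz, day2_fate = day2_fate,
                 clipped = FALSE),
            class = "pf_truth_cell")
}

## skew-normal envelope with unit peak; skew 0 reduces to a Gaussian.
## Location parameter is shifted so the profile's mean stays at `center`
## for any shape, keeping the ground-truth center interpretable as a COM.
skew_envelope <- function(x, center, width, shape = 0) {
  scale <- width / 4
  if (shape == 0) {
    e <- exp(-((x - center)^2) / (2 * scale^2))
  } else {
    delta <- shape / sqrt(1 + shape^2)
    mean_off <- scale * delta * sqrt(2 / pi)  # mean of skew-normal minus location
    z <- (x - (center - mean_off)) / scale
    e <- dnorm(z) * pnorm(shape * z)
    e <- e / max(e)
  }
  e
}

## GCaMP6f-like kernel: linear rise then exponential decay, sum-normalized.
## Returned with its temporal centroid so callers can recenter the
## convolution (keeps the spatial COM of a symmetric envelope at the true
## center instead of dragging it forward by ~tau * speed).
calcium_kernel <- function(frame_rate, tau_decay_s = 0.4, rise_s = 0.05) {
  dt <- 1 / frame_rate
  t <- seq(0, 5 * tau_decay_s, by = dt)
  k <- pmin(t / max(rise_s, dt / 10), 1) * exp(-pmax(t - rise_s, 0) / tau_decay_s)
  k <- k / sum(k)
  list(k = k, centroid_frames = sum(seq_along(k) * k) - 1)
}

## convolve activity with the kernel, recentered at the kernel centroid
convolve_centered <- function(a, kernel) {
  n <- length(a)
  k <- kernel$k
  y <- convolve(a, rev(k), type = "open")  # y[m] = sum_j a[j] k[m - j + 1]
  c0 <- round(kernel$centroid_frames)
  y[seq_len(n) + c0]
}

#' Synthesize the \eqn{\Delta}F/F trace of one place cell
#'
#' On each lap at or after a field's onset lap the field emits, with
#' probability `reliability`, a transient whose spatial envelope is a
#' (possibly skewed) Gaussian centered at
#' `center + drift * (lap - onset_lap)`, scaled to the field amplitude and
#' convolved with a GCaMP6f-like calcium kernel (linear 50 ms rise,
#' 0.4 s exponential decay). Out-of-field transients are added as a Poisson
#' process at `oof_rate_hz`, and Gaussian noise of `noise_sigma` on top.
#' Drift that pushes the center off the track truncates the envelope at the
#' track edge and flags the cell.
#'
#' @param truth a [ground_truth_cell()].
#' @param behavior a `"pf_behavior"` trace.
#' @param noise_sigma additive Gaussian noise sd (\eqn{\Delta}F/F units).
#' @param seed RNG seed.
#' @param tau_decay_s,rise_s calcium kernel parameters (s).
#' @return A list: `dff` (trace), `truth` (with `clipped` updated),
#'   `lap_emitted` (logical matrix field x lap).
#' @export
synthesize_cell <- function(truth, behavior, noise_sigma = 0.05, seed = 1L,
                            tau_decay_s = 0.4, rise_s = 0.05) {
  stopifnot(inherits(truth, "pf_truth_cell"), inherits(behavior, "pf_behavior"))
  set.seed(seed)
  n <- length(behavior$time_s)
  L <- behavior$track_length_cm
  kern <- calcium_kernel(behavior$frame_rate_hz, tau_decay_s, rise_s)
  a <- numeric(n)
  n_fields <- length(truth$centers_cm)
  emitted <- matrix(FALSE, n_fields, behavior$n_laps)
  clipped <- FALSE
  for (f in seq_len(n_fields)) {
    for (l in seq(truth$onset_laps[f], behavior$n_laps)) {
      if (runif(1) > truth$reliability) next
      center_l <- truth$centers_cm[f] +
        truth$drift_cm_per_lap[f] * (l - truth$onset_laps[f])
      if (center_l < 0 || center_l > L) clipped <- TRUE
      idx <- which(behavior$lap_index == l & !behavior$is_pause)
      e <- skew_envelope(behavior$position_cm[idx], center_l,
                         truth$widths_cm[f], truth$skew_param)
      a[idx] <- a[idx] + truth$amplitudes_dff[f] * e
      emitted[f, l] <- TRUE
    }
  }
  dff <- convolve_centered(a, kern)
  ## out-of-field transients: kernel-shaped events at random frames
  if (truth$oof_rate_hz > 0) {
    n_oof <- rpois(1, truth$oof_rate_hz * max(behavior$time_s))
    if (n_oof > 0) {
      amp0 <- if (length(truth$amplitudes_dff)) mean(truth$amplitudes_dff) else 1
      frames <- sample.int(n, n_oof, replace = TRUE)
      amps <- runif(n_oof, 0.4, 1) * amp0
      kshape <- kern$k / max(kern$k)
      for (j in seq_len(n_oof)) {
        idx <- frames[j]:min(n, frames[j] + length(kshape) - 1L)
        dff[idx] <- dff[idx] + amps[j] * kshape[seq_along(idx)]
      }
    }
  }
  if (noise_sigma > 0) dff <- dff + rnorm(n, 0, noise_sigma)
  truth$clipped <- clipped
  list(dff = dff, truth = truth, lap_emitted = emitted)
}

#' Synthesize a full session
#'
#' Generates behavior and stacks per-cell traces into a neuron x frame
#' \eqn{\Delta}F/F matrix. One master seed; per-cell child seeds are derived
#' deterministically so adding a cell never perturbs earlier cells.
#'
#' @param cfg a [behavior_config()].
#' @param cells list of [ground_truth_cell()]s (may be empty).
#' @param noise_sigma per-cell additive noise sd.
#' @param seed master RNG seed.
#' @return An object of class `"pf_session"`: `behavior`, `dff`
#'   (n_cells x n_frames), `truth` (list), `noise_sigma`, `seed`.
#' @export
synthesize_session <- function(cfg, cells, noise_sigma = 0.05, seed = 1L) {
  behavior <- generate_behavior(cfg, derive_seed(seed, 0L))
  n <- length(behavior$time_s)
  dff <- matrix(0, nrow = length(cells), ncol = n)
  truth <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    out <- synthesize_cell(cells[[i]], behavior, noise_sigma,
                           seed = derive_seed(seed, i))
    dff[i, ] <- out$dff
    truth[[i]] <- out$truth
  }
  structure(list(behavior = behavior, dff = dff, truth = truth,
                 noise_sigma = noise_sigma, seed = seed, cfg = cfg),
            class = "pf_session")
}

#' @export
print.pf_session <- function(x, ...) {
  cat(sprintf("pf_session: %d cells x %d frames, %d laps, seed %d\n",
              nrow(x$dff), ncol(x$dff), x$behavior$n_laps, x$seed))
  invisible(x)
}

#' Synthesize a paired pair of daily sessions
#'
#' Day 2 reuses day-1 field centers for cells with `day2_fate = "stable"`
#' (fresh onset laps drawn from an early-onset distribution, emulating the
#' rapid re-emergence of retrieved fields), redraws centers uniformly for
#' `"remap"` cells, and silences `"silent"` cells. Cell indices map
#' identically across days.
#'
#' @param cfg a [behavior_config()] used for both days.
#' @param cells day-1 ground truth cells.
#' @param stable_fraction if non-NULL, reassigns fates: stable with this
#'   probability, remap otherwise.
#' @param seed master seed.
#' @param noise_sigma additive noise sd.
#' @param day2_p_instant probability a stable field re-emerges on lap 1 of
#'   day 2 (remaining onsets geometric with `day2_onset_decay`).
#' @param day2_onset_decay geometric decay of non-instant day-2 onsets.
#' @return A list with elements `day1` and `day2`, both `"pf_session"`.
#' @export
synthesize_paired_days <- function(cfg, cells, stable_fraction = NULL,
                                   seed = 1L, noise_sigma = 0.05,
                                   day2_p_instant = 0.5,
                                   day2_onset_decay = 0.35) {
  stopifnot(is.null(stable_fraction) ||
              (stable_fraction >= 0 && stable_fraction <= 1))
  set.seed(derive_seed(seed, 999983L))
  if (!is.null(stable_fraction)) {
    fates <- ifelse(runif(length(cells)) < stable_fraction, "stable", "remap")
    for (i in seq_along(cells)) cells[[i]]$day2_fate <- fates[i]
  }
  draw_onset <- function() {
    if (runif(1) < day2_p_instant) 1L
    else as.integer(2L + stats::rgeom(1, day2_onset_decay))
  }
  cells2 <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    c2 <- cells[[i]]
    if (c2$day2_fate == "silent") {
      c2$amplitudes_dff <- rep(0, length(c2$amplitudes_dff))
    } else if (c2$day2_fate == "remap") {
      c2$centers_cm <- runif(length(c2$centers_cm), 0.05, 0.95) *
        cfg$track_length_cm
      c2$onset_laps <- vapply(c2$onset_laps, function(o) {
        as.integer(min(draw_onset() + 1L, cfg$n_laps))
      }, integer(1)) # remapped fields emerge like new ones
    } else {
      c2$onset_laps <- vapply(c2$onset_laps, function(o) {
        as.integer(min(draw_onset(), cfg$n_laps))
      }, integer(1))
    }
    cells2[[i]] <- c2
  }
  list(day1 = synthesize_session(cfg, cells, noise_sigma,
                                 seed = derive_seed(seed, 1000003L)),
       day2 = synthesize_session(cfg, cells2, noise_sigma,
                                 seed = derive_seed(seed, 1000033L)))
}
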