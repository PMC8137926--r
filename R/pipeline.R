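#' Run the full lap-by-lap place-field analysis on a session
#'
#' The central fitting routine: for every cell it (1) detects significant
#' calcium transients (baseline correction, 2\eqn{\sigma}/0.5\eqn{\sigma}
#' events, false-positive amplitude/duration filter), (2) builds the
#' lap-by-bin activity matrix on running periods, (3) detects place fields
#' (candidate threshold, four criteria, lap-shuffle bootstrap), and (4) for
#' each significant field computes the lap-wise COM series, weighted COM,
#' spatial precision, skewness and width series, out/in ratio, onset lap,
#' edge-clipping flag, per-field shift regression and session shift.
#'
#' @param session a `"pf_session"` (or a list with `dff` matrix and
#'   `behavior`).
#' @param config a [pf_config()].
#' @param seed seed for the bootstrap.
#' @param keep_traces keep the per-cell significant-transient traces in the
#'   result (needed for decoding; memory-heavy for large sessions).
#' @param corrected set TRUE when `session$dff` is already
#'   baseline-corrected.
#' @return An object of class `"pf_analysis"`: `fields` (one row per
#'   significant field with all summary metrics), `series` (per-field COM
#'   data.frames), `skew_series`, `width_series`, `matrices` (per-cell
#'   lap-by-bin matrices), `mean_maps`, `candidates` (all candidates incl.
#'   rejected), `sig_traces` (if kept), `behavior`, `config`, `seed`.
#' @export
pf_analyze <- function(session, config = pf_config(), seed = 1L,
                       keep_traces = FALSE, corrected = FALSE) {
  behavior <- session$behavior
  n_cells <- nrow(session$dff)
  bw <- config$track_length_cm / config$n_bins
  matrices <- vector("list", n_cells)
  sig_traces <- if (keep_traces) {
    matrix(0, n_cells, ncol(session$dff))
  } else NULL
  all_fields <- list()
  all_cand <- list()
  series <- list()
  skew_series <- list()
  width_series <- list()
  for (i in seq_len(n_cells)) {
    tr <- detect_transients(session$dff[i, ], behavior$frame_rate_hz,
                            config, corrected = corrected)
    if (keep_traces) sig_traces[i, ] <- tr$sig_trace
    mat <- lap_bin_matrix(tr$sig_trace, behavior, config$n_bins,
                          config$velocity_threshold_cm_s)
    matrices[[i]] <- mat
    evpos <- event_positions(tr, behavior)
    al_fn <- function(s, e) {
      ext <- c((s - 1) * bw, e * bw)
      inb <- evpos$peak_pos_cm >= ext[1] & evpos$peak_pos_cm < ext[2]
      out <- rep(FALSE, behavior$n_laps)
      out[unique(evpos$lap[inb & evpos$lap >= 1])] <- TRUE
      out
    }
    fields <- detect_place_fields(mat, config, seed = derive_seed(seed, i),
                                  active_laps_fn = al_fn)
    if (nrow(fields) > 0) {
      fields$cell <- i
      all_cand[[length(all_cand) + 1L]] <- fields
    }
    sig <- fields[fields$significant, , drop = FALSE]
    for (k in seq_len(nrow(sig))) {
      fld <- sig[k, ]
      ext <- c((fld$bin_start - 1) * bw, fld$bin_end * bw)
      masked <- mask_to_field(tr, ext, behavior)
      mmat <- lap_bin_matrix(masked$sig_trace, behavior, config$n_bins,
                             config$velocity_threshold_cm_s)
      ## COM/skew over all bins of the masked matrix: retained transients
      ## keep their full spatial footprint (see ?com_per_lap)
      com_df <- com_per_lap(mmat)
      if (nrow(com_df) == 0) next
      cw <- weighted_com(com_df$com, com_df$peak)
      sp <- if (nrow(com_df) >= 2) {
        spatial_precision(com_df$com, com_df$peak)
      } else NA_real_
      shift <- field_shift_regression(com_df, config$shift_min_laps,
                                      config$p_threshold)
      onset <- onset_lap(masked$event_laps, config$onset_rule,
                         config$onset_window)
      fid <- length(series) + 1L
      series[[fid]] <- com_df
      skew_series[[fid]] <- skewness_per_lap(mmat)
      width_series[[fid]] <- width_per_lap(mmat, fld)
      all_fields[[fid]] <- data.frame(
        field = fid, cell = i, bin_start = fld$bin_start,
        bin_end = fld$bin_end, width_cm = fld$width_cm,
        peak_dff = fld$peak_dff, p_boot = fld$p_boot,
        multi_field_rank = fld$multi_field_rank,
        onset_lap = if (is.na(onset)) NA_integer_ else onset,
        com_w = cw, sp = sp,
        out_in = tryCatch(out_in_ratio(mat, fld), error = function(e) NA_real_),
        is_clipped = is_edge_clipped(cw, fld$width_cm,
                                     config$track_length_cm, bw),
        n_active_laps = nrow(com_df),
        slope_cm_per_lap = shift$slope_cm_per_lap,
        shift_p = shift$p_value, shift_class = shift$shift_class,
        session_shift = as.numeric(session_shift(com_df,
                                                 config$shift_window)))
    }
  }
  fields <- do.call(rbind, c(all_fields, list(make.row.names = FALSE)))
  if (is.null(fields)) {
    fields <- data.frame(field = integer(0), cell = integer(0),
                         bin_start = integer(0), bin_end = integer(0),
                         width_cm = numeric(0), peak_dff = numeric(0),
                         p_boot = numeric(0), multi_field_rank = integer(0),
                         onset_lap = integer(0), com_w = numeric(0),
                         sp = numeric(0), out_in = numeric(0),
                         is_clipped = logical(0), n_active_laps = integer(0),
                         slope_cm_per_lap = numeric(0), shift_p = numeric(0),
                         shift_class = character(0),
                         session_shift = numeric(0))
  }
  structure(list(fields = fields, series = series,
                 skew_series = skew_series, width_series = width_series,
                 matrices = matrices,
                 mean_maps = t(vapply(matrices, colMeans,
                                      numeric(config$n_bins))),
                 candidates = do.call(rbind, all_cand),
                 sig_traces = sig_traces, behavior = behavior,
                 config = config, seed = seed, n_cells = n_cells),
            class = "pf_analysis")
}

#' @export
print.pf_analysis <- function(x, ...) {
  cat(sprintf("pf_analysis: %d cells, %d significant place fields (%d laps)\n",
              x$n_cells, nrow(x$fields), x$behavior$n_laps))
  invisible(x)
}

#' @export
summary.pf_analysis <- function(object, ...) {
  f <- object$fields
  cls <- table(factor(f$shift_class,
                      levels = c("backward", "forward", "nonsignificant",
                                 "excluded")))
  out <- list(
    n_cells = object$n_cells,
    n_fields = nrow(f),
    n_place_cells = length(unique(f$cell)),
    fraction_instant = if (nrow(f)) mean(f$onset_lap == 1, na.rm = TRUE)
                       else NA_real_,
    median_onset_lap = if (nrow(f)) median(f$onset_lap, na.rm = TRUE)
                       else NA_real_,
    mean_width_cm = if (nrow(f)) mean(f$width_cm) else NA_real_,
    shift_classes = cls,
    fraction_shifting = if (nrow(f)) {
      mean(f$shift_class %in% c("backward", "forward"))
    } else NA_real_,
    mean_session_shift = if (nrow(f)) {
      mean(f$session_shift, na.rm = TRUE)
    } else NA_real_)
  class(out) <- "summary.pf_analysis"
  out
}

#' @export
print.summary.pf_analysis <- function(x, ...) {
  cat(sprintf("%d cells, %d place cells with %d significant fields\n",
              x$n_cells, x$n_place_cells, x$n_fields))
  cat(sprintf("  instant (lap-1 onset) fraction: %.2f; median onset lap: %g\n",
              x$fraction_instant, x$median_onset_lap))
  cat(sprintf("  mean width: %.1f cm; mean session shift: %.3f cm/lap\n",
              x$mean_width_cm, x$mean_session_shift))
  cat(sprintf("  significantly shifting: %.0f%% (backward %d, forward %d)\n",
              100 * x$fraction_shifting, x$shift_classes["backward"],
              x$shift_classes["forward"]))
  invisible(x)
}

#' @export
plot.pf_analysis <- function(x, what = c("maps", "onsets", "shifts"), ...) {
  what <- match.arg(what)
  f <- x$fields
  if (what == "maps") {
    cells <- unique(f$cell[order(f$com_w)])
    if (length(cells) == 0) stop("no fields to plot")
    m <- x$mean_maps[cells, , drop = FALSE]
    m <- m / pmax(apply(m, 1, max), 1e-12)
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    xlab = "track position (fraction)", ylab = "cell (sorted by COM)",
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  } else if (what == "onsets") {
    graphics::hist(f$onset_lap, breaks = seq(0.5, max(f$onset_lap,
                                                      na.rm = TRUE) + 0.5),
                   xlab = "onset lap", main = "place-field onset laps", ...)
  } else {
    graphics::hist(f$session_shift, breaks = 20,
                   xlab = "session shift (cm/lap)",
                   main = "per-field session shifts", ...)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}

#' Long-format per-lap metrics of all fields
#'
#' @param analysis a `"pf_analysis"`.
#' @return A data.frame `field`, `cell`, `lap`, `com`, `peak`, `skew`,
#'   `width_cm`, `width_norm` (NA where a metric is undefined on a lap).
#' @export
field_metrics <- function(analysis) {
  out <- lapply(seq_along(analysis$series), function(fid) {
    cdf <- analysis$series[[fid]]
    sk <- analysis$skew_series[[fid]]
    wd <- analysis$width_series[[fid]]
    df <- data.frame(field = fid,
                     cell = analysis$fields$cell[fid],
                     lap = cdf$lap, com = cdf$com, peak = cdf$peak)
    df$skew <- sk$skew[match(df$lap, sk$lap)]
    df$width_cm <- wd$width_cm[match(df$lap, wd$lap)]
    df$width_norm <- wd$width_norm[match(df$lap, wd$lap)]
    df
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(field = integer(0), cell = integer(0),
                      lap = integer(0), com = numeric(0), peak = numeric(0),
                      skew = numeric(0), width_cm = numeric(0),
                      width_norm = numeric(0))
  }
  out
}

#' Population shift curve from an analysis
#'
#' Convenience wrapper: feeds the analysis' unclipped fields into
#' [population_shift_curve()].
#'
#' @param analysis a `"pf_analysis"`.
#' @param exclude_clipped drop edge-clipped fields.
#' @param ... passed to [population_shift_curve()].
#' @return A `"pf_popcurve"`.
#' @export
analysis_shift_curve <- function(analysis, exclude_clipped = TRUE, ...) {
  keep <- if (exclude_clipped) which(!analysis$fields$is_clipped)
          else seq_len(nrow(analysis$fields))
  population_shift_curve(analysis$series[keep],
                         analysis$fields$onset_lap[keep],
                         config = analysis$config, ...)
}
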