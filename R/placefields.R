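#' Lap-by-bin activity matrix
#'
#' Bins a significant-transient-only trace by lap and track position: the
#' mean \eqn{\Delta}F/F of in-mask (running, non-pause) samples in each of
#' `n_bins` position bins on each lap. Bins without samples on a lap are 0
#' and flagged in the occupancy attribute.
#'
#' @param trace per-frame activity (typically the significant-transient-only
#'   trace).
#' @param behavior a `"pf_behavior"` object.
#' @param n_bins number of spatial bins.
#' @param velocity_threshold_cm_s immobility threshold.
#' @return An n_laps x n_bins matrix with attributes `bin_centers_cm`,
#'   `bin_width_cm`, `occupancy` (sample counts per cell of the matrix), and
#'   `lap_ok` (laps with at least one in-mask sample).
#' @export
lap_bin_matrix <- function(trace, behavior, n_bins = 50,
                           velocity_threshold_cm_s = 0.2) {
  stopifnot(length(trace) == length(behavior$time_s))
  bw <- behavior$track_length_cm / n_bins
  mask <- locomotion_mask(behavior$velocity_cm_s, velocity_threshold_cm_s) &
    !behavior$is_pause & behavior$lap_index >= 1
  idx <- which(mask)
  nl <- behavior$n_laps
  bin <- pmin(floor(behavior$position_cm[idx] / bw) + 1L, n_bins)
  lap <- behavior$lap_index[idx]
  key <- (lap - 1L) * n_bins + bin
  sums <- numeric(nl * n_bins)
  cnts <- numeric(nl * n_bins)
  agg <- rowsum(cbind(trace[idx], 1), key)
  at <- as.integer(rownames(agg))
  sums[at] <- agg[, 1]
  cnts[at] <- agg[, 2]
  m <- matrix(ifelse(cnts > 0, sums / pmax(cnts, 1), 0),
              nrow = nl, ncol = n_bins, byrow = TRUE)
  occ <- matrix(cnts, nrow = nl, ncol = n_bins, byrow = TRUE)
  attr(m, "bin_centers_cm") <- (seq_len(n_bins) - 0.5) * bw
  attr(m, "bin_width_cm") <- bw
  attr(m, "occupancy") <- occ
  attr(m, "lap_ok") <- rowSums(occ) > 0
  m
}

#' Candidate place-field extents from a mean activity map
#'
#' The baseline is the mean of the `n_baseline_bins` lowest bins, the peak
#' the global maximum; candidates are maximal runs of contiguous bins all
#' exceeding `baseline + threshold_frac * (peak - baseline)`. No wraparound
#' across the track ends.
#'
#' @param mean_map mean \eqn{\Delta}F/F per bin, over all laps.
#' @param threshold_frac fraction of the peak-minus-baseline difference.
#' @param n_baseline_bins bins averaged into the baseline.
#' @return A data.frame `bin_start`, `bin_end` (1-based, inclusive), ordered
#'   by position; zero rows when the map is flat.
#' @export
detect_candidates <- function(mean_map, threshold_frac = 0.15,
                              n_baseline_bins = 12) {
  baseline <- mean(sort(mean_map)[seq_len(min(n_baseline_bins,
                                              length(mean_map)))])
  peak <- max(mean_map)
  if (peak <= baseline) {
    return(data.frame(bin_start = integer(0), bin_end = integer(0)))
  }
  thr <- baseline + threshold_frac * (peak - baseline)
  above <- mean_map > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(bin_start = starts[keep], bin_end = ends[keep])
}

#' Evaluate the four place-field criteria on a candidate extent
#'
#' 1. width strictly between the configured bounds (20--150 cm);
#' 2. at least one in-field mean-map value above 0.1 \eqn{\Delta}F/F;
#' 3. in-field mean at least three times the out-of-field mean;
#' 4. in-field transients present on at least `pf_min_laps` laps (laps with
#'    a nonzero in-field bin when no event table is supplied).
#'
#' @param candidate one-row data.frame with `bin_start`, `bin_end`.
#' @param matrix lap-by-bin matrix from [lap_bin_matrix()].
#' @param config a [pf_config()].
#' @param active_laps optional logical vector (length n_laps): laps with a
#'   significant transient peaking inside the extent.
#' @param mean_map precomputed `colMeans(matrix)` (avoids recomputation in
#'   bootstrap loops).
#' @return A list: `pass` plus per-criterion logicals `width_ok`, `peak_ok`,
#'   `ratio_ok`, `laps_ok`, and the measured `width_cm`, `in_mean`,
#'   `out_mean`, `n_active_laps`.
#' @export
apply_criteria <- function(candidate, matrix, config = pf_config(),
                           active_laps = NULL, mean_map = NULL) {
  bw <- attr(matrix, "bin_width_cm")
  s <- candidate$bin_start; e <- candidate$bin_end
  if (is.null(mean_map)) mean_map <- colMeans(matrix)
  width <- (e - s + 1L) * bw
  in_mean <- mean(mean_map[s:e])
  out_mean <- if (e - s + 1L < length(mean_map)) {
    mean(mean_map[-(s:e)])
  } else 0
  if (is.null(active_laps)) {
    active_laps <- rowSums(matrix[, s:e, drop = FALSE] > 0) > 0
  }
  checks <- list(
    width_ok = width > config$pf_width_min_cm & width < config$pf_width_max_cm,
    peak_ok = max(mean_map[s:e]) > config$pf_min_peak_dff,
    ratio_ok = out_mean == 0 || in_mean > config$pf_min_ratio * out_mean,
    laps_ok = sum(active_laps) >= config$pf_min_laps)
  c(checks,
    list(pass = all(unlist(checks)), width_cm = width, in_mean = in_mean,
         out_mean = out_mean, n_active_laps = sum(active_laps)))
}

## circularly shift each lap's bin vector by an independent offset
shift_laps <- function(m, offsets) {
  nb <- ncol(m)
  out <- m
  for (r in seq_len(nrow(m))) {
    o <- offsets[r]
    if (o > 0) out[r, ] <- m[r, c((nb - o + 1L):nb, seq_len(nb - o))]
  }
  out
}

#' Bootstrap p-value for a candidate place field
#'
#' Null distribution from circularly shifting each lap's bin vector by an
#' independent uniform offset (preserving within-lap transient structure),
#' rerunning candidate detection and the four criteria, and scoring whether
#' a qualifying field with in-field mean at least as large as the observed
#' one exists. p = (1 + #successes) / (1 + n_iter).
#'
#' @param matrix lap-by-bin matrix.
#' @param candidate one-row data.frame `bin_start`, `bin_end`.
#' @param n_iter shuffle iterations (>= 1; < 100 warns).
#' @param seed RNG seed.
#' @param config a [pf_config()].
#' @param early_stop stop shuffling once enough null successes have
#'   accumulated that the p-value must exceed `config$p_threshold` whatever
#'   the remaining iterations return; the sequential estimate
#'   (1 + successes)/(1 + iterations run) is returned. Classification at the
#'   threshold is unchanged.
#' @return The bootstrap p-value.
#' @export
bootstrap_pvalue <- function(matrix, candidate, n_iter = 1000, seed = 1L,
                             config = pf_config(), early_stop = TRUE) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (n_iter < 100) warning("n_iter < 100 gives unstable p-values")
  set.seed(seed)
  obs <- apply_criteria(candidate, matrix, config)
  nb <- ncol(matrix)
  nl <- nrow(matrix)
  stop_at <- ceiling(config$p_threshold * (1 + n_iter))
  succ <- 0L
  it <- 0L
  ## vectorized per-lap circular shift: linear-index arithmetic, no copies
  rowm <- matrix(seq_len(nl), nl, nb)
  colbase <- matrix(0:(nb - 1), nl, nb, byrow = TRUE)
  nbase <- min(config$pf_baseline_bins, nb)
  while (it < n_iter) {
    it <- it + 1L
    off <- sample.int(nb, nl, replace = TRUE) - 1L
    sm <- matrix(matrix[rowm + nl * ((colbase - off[rowm]) %% nb)], nl, nb)
    mm <- colMeans(sm)
    if (boot_null_success(sm, mm, nl, nb, nbase, config, obs$in_mean)) {
      succ <- succ + 1L
    }
    if (early_stop && succ >= stop_at) break
  }
  (1 + succ) / (1 + it)
}

## lean criteria scan over the candidates of one shuffled matrix; TRUE when
## a qualifying field with in-field mean >= the observed one exists.
## Mirrors detect_candidates() + apply_criteria(); kept allocation-free for
## the bootstrap hot loop.
boot_null_success <- function(sm, mm, nl, nb, nbase, config, obs_in_mean) {
  baseline <- mean(sort(mm, partial = nbase)[seq_len(nbase)])
  peak <- max(mm)
  if (peak <= baseline) return(FALSE)
  thr <- baseline + config$pf_threshold_frac * (peak - baseline)
  above <- mm > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bw <- config$track_length_cm / nb
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    width <- (e - s + 1L) * bw
    if (width <= config$pf_width_min_cm || width >= config$pf_width_max_cm) next
    in_mean <- mean(mm[s:e])
    if (in_mean < obs_in_mean) next
    if (max(mm[s:e]) <= config$pf_min_peak_dff) next
    out_mean <- (sum(mm) - sum(mm[s:e])) / (nb - (e - s + 1L))
    if (out_mean > 0 && in_mean <= config$pf_min_ratio * out_mean) next
    active <- sum(.rowSums(sm[, s:e, drop = FALSE], nl, e - s + 1L) > 0)
    if (active < config$pf_min_laps) next
    return(TRUE)
  }
  FALSE
}

#' Detect significant place fields for one cell
#'
#' Candidate detection on the mean map, the four criteria, then the
#' bootstrap test on every candidate that passes them. Multiple candidates
#' per cell are tested independently and ranked by track position.
#'
#' @param matrix lap-by-bin matrix from [lap_bin_matrix()].
#' @param config a [pf_config()].
#' @param seed seed for the bootstrap.
#' @param active_laps_fn optional `function(bin_start, bin_end)` returning
#'   the logical active-lap vector from the cell's event table; defaults to
#'   nonzero in-field bins.
#' @return A data.frame, one row per candidate: extent, width, criterion
#'   flags, `p_boot` (NA when the criteria already fail), `significant`,
#'   `multi_field_rank`.
#' @export
detect_place_fields <- function(matrix, config = pf_config(), seed = 1L,
                                active_laps_fn = NULL) {
  mean_map <- colMeans(matrix)
  cand <- detect_candidates(mean_map, config$pf_threshold_frac,
                            config$pf_baseline_bins)
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    al <- if (is.null(active_laps_fn)) NULL else {
      active_laps_fn(cand$bin_start[k], cand$bin_end[k])
    }
    chk <- apply_criteria(cand[k, ], matrix, config, active_laps = al)
    p <- NA_real_
    if (chk$pass) {
      p <- bootstrap_pvalue(matrix, cand[k, ], config$n_boot,
                            seed = derive_seed(seed, k), config = config)
    }
    data.frame(bin_start = cand$bin_start[k], bin_end = cand$bin_end[k],
               width_cm = chk$width_cm, peak_dff = max(mean_map[cand$bin_start[k]:cand$bin_end[k]]),
               in_mean = chk$in_mean, out_mean = chk$out_mean,
               width_ok = chk$width_ok, peak_ok = chk$peak_ok,
               ratio_ok = chk$ratio_ok, laps_ok = chk$laps_ok,
               n_active_laps = chk$n_active_laps, p_boot = p,
               significant = chk$pass && !is.na(p) && p < config$p_threshold)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(bin_start = integer(0), bin_end = integer(0),
                      width_cm = numeric(0), peak_dff = numeric(0),
                      in_mean = numeric(0), out_mean = numeric(0),
                      width_ok = logical(0), peak_ok = logical(0),
                      ratio_ok = logical(0), laps_ok = logical(0),
                      n_active_laps = integer(0), p_boot = numeric(0),
                      significant = logical(0))
  }
  out$multi_field_rank <- seq_len(nrow(out))
  out
}

#' Per-event lap and peak position
#'
#' Locates each significant transient's peak sample and reports its lap and
#' track position; used to assign events to fields.
#'
#' @param transients a `"pf_transients"` object.
#' @param behavior a `"pf_behavior"` object.
#' @return A data.frame `event`, `lap`, `peak_frame`, `peak_pos_cm`.
#' @export
event_positions <- function(transients, behavior) {
  ev <- transients$events
  if (nrow(ev) == 0) {
    return(data.frame(event = integer(0), lap = integer(0),
                      peak_frame = integer(0), peak_pos_cm = numeric(0)))
  }
  pk <- vapply(seq_len(nrow(ev)), function(k) {
    idx <- ev$onset[k]:ev$offset[k]
    idx[which.max(transients$sig_trace[idx])]
  }, integer(1))
  data.frame(event = seq_len(nrow(ev)), lap = behavior$lap_index[pk],
             peak_frame = pk, peak_pos_cm = behavior$position_cm[pk])
}

#' Restrict transients to a field
#'
#' Keeps only transients whose peak-sample position lies within the field
#' extent; transients outside the defined field are removed from all
#' per-field metrics.
#'
#' @param transients a `"pf_transients"` object.
#' @param extent_cm numeric length-2: field start/end in cm (half-open).
#' @param behavior a `"pf_behavior"` object.
#' @return A list: `sig_trace` (in-field-only trace), `events` (subset),
#'   `event_laps` (laps with at least one in-field event, logical).
#' @export
mask_to_field <- function(transients, extent_cm, behavior) {
  pos <- event_positions(transients, behavior)
  keep <- pos$peak_pos_cm >= extent_cm[1] & pos$peak_pos_cm < extent_cm[2]
  ev <- transients$events[keep, , drop = FALSE]
  trace <- numeric(length(transients$sig_trace))
  for (k in seq_len(nrow(ev))) {
    idx <- ev$onset[k]:ev$offset[k]
    trace[idx] <- transients$sig_trace[idx]
  }
  lap_active <- rep(FALSE, behavior$n_laps)
  lap_active[unique(pos$lap[keep & pos$lap >= 1])] <- TRUE
  list(sig_trace = trace, events = ev, event_laps = lap_active)
}

#' Edge-clipping exclusion rule
#'
#' A field is clipped when the distance between a track edge and the field's
#' weighted COM is at least one bin shorter than half the field width;
#' clipped fields are excluded from shift, skewness, and width analyses.
#'
#' @param com_w_cm weighted COM of the field (cm).
#' @param width_cm field width (cm).
#' @param track_length_cm track length (cm).
#' @param bin_width_cm spatial bin width (cm).
#' @return TRUE when the field is clipped (boundary inclusive).
#' @export
is_edge_clipped <- function(com_w_cm, width_cm, track_length_cm = 300,
                            bin_width_cm = 6) {
  min(com_w_cm, track_length_cm - com_w_cm) <= (width_cm / 2 - bin_width_cm)
}
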