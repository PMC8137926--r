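#' Lap-wise center of mass of a field
#'
#' For each traversal n with in-field activity, the activity-weighted mean
#' position COM_n = sum_i DF_i x_i / sum_i DF_i over the field's bins, where
#' DF_i is the somatic \eqn{\Delta}F/F in bin i and x_i the bin center.
#' Laps with zero in-field activity are absent from the result, not zero.
#' A_n, the peak in-field \eqn{\Delta}F/F on the traversal, is reported
#' alongside as the weight used by downstream weighted averages.
#'
#' When the matrix was built from a field-masked trace (only transients
#' peaking inside the field retained), pass `field = NULL` to integrate over
#' all bins: a retained transient's spatial footprint may legitimately
#' extend past the extent edge, and truncating it would bias the COM of
#' drifting fields toward the extent center.
#'
#' @param matrix lap-by-bin matrix (in-field masked trace).
#' @param field one-row data.frame (or list) with `bin_start`, `bin_end`;
#'   `NULL` uses all bins.
#' @return A data.frame `lap`, `com` (cm), `peak` (A_n).
#' @export
com_per_lap <- function(matrix, field = NULL) {
  x <- attr(matrix, "bin_centers_cm")
  cols <- if (is.null(field)) seq_len(ncol(matrix)) else {
    field$bin_start:field$bin_end
  }
  sub <- matrix[, cols, drop = FALSE]
  tot <- rowSums(sub)
  active <- which(tot > 0)
  com <- as.numeric(sub[active, , drop = FALSE] %*% x[cols]) / tot[active]
  data.frame(lap = active, com = com,
             peak = apply(sub[active, , drop = FALSE], 1, max))
}

#' Amplitude-weighted COM across traversals
#'
#' COM_w = sum_n A_n COM_n / sum_n A_n, weighting each traversal's COM by
#' its peak transient \eqn{\Delta}F/F.
#'
#' @param com COM_n series (cm).
#' @param peaks A_n series, same length.
#' @return COM_w (cm).
#' @export
weighted_com <- function(com, peaks) {
  stopifnot(length(com) == length(peaks))
  if (sum(peaks) <= 0) stop("all traversal peaks are zero; COM_w undefined")
  sum(peaks * com) / sum(peaks)
}

#' Spatial precision
#'
#' The inverse of the amplitude-weighted standard deviation of the lap-wise
#' COMs: SP = 1 / sqrt( sum_n A_n (COM_n - COM_w)^2 / sum_n A_n ). Identical
#' COMs give zero variance; `Inf` is returned so population summaries can
#' filter the degenerate case.
#'
#' @inheritParams weighted_com
#' @return SP (1/cm); `Inf` when the weighted variance is zero.
#' @export
spatial_precision <- function(com, peaks) {
  if (length(com) < 2) stop("spatial precision needs >= 2 active laps")
  cw <- weighted_com(com, peaks)
  v <- sum(peaks * (com - cw)^2) / sum(peaks)
  if (v == 0) return(Inf)
  1 / sqrt(v)
}

#' Lap-wise skewness of the field profile
#'
#' Third standardized moment of the in-field \eqn{\Delta}F/F profile on each
#' lap: sum_i (DF_i / sum DF_i) ((x_i - COM_n) / sigma)^3 with sigma the
#' activity-weighted standard deviation of position. Laps with fewer than 3
#' nonzero bins or zero sigma are excluded.
#'
#' @inheritParams com_per_lap
#' @return A data.frame `lap`, `skew`.
#' @export
skewness_per_lap <- function(matrix, field = NULL) {
  cols <- if (is.null(field)) seq_len(ncol(matrix)) else {
    field$bin_start:field$bin_end
  }
  x <- attr(matrix, "bin_centers_cm")[cols]
  sub <- matrix[, cols, drop = FALSE]
  out <- lapply(seq_len(nrow(sub)), function(l) {
    df <- sub[l, ]
    if (sum(df > 0) < 3) return(NULL)
    w <- df / sum(df)
    com <- sum(w * x)
    s <- sqrt(sum(w * (x - com)^2))
    if (s == 0) return(NULL)
    data.frame(lap = l, skew = sum(w * ((x - com) / s)^3))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(lap = integer(0), skew = numeric(0)) else out
}

#' Lap-wise field width
#'
#' Per active lap, the inclusive span from the first to the last in-field
#' bin with activity, in cm; plus the series normalized to the field's
#' across-lap mean width (mean 1 over active laps).
#'
#' @inheritParams com_per_lap
#' @return A data.frame `lap`, `width_cm`, `width_norm`.
#' @export
width_per_lap <- function(matrix, field) {
  bw <- attr(matrix, "bin_width_cm")
  sub <- matrix[, field$bin_start:field$bin_end, drop = FALSE]
  out <- lapply(seq_len(nrow(sub)), function(l) {
    nz <- which(sub[l, ] > 0)
    if (length(nz) == 0) return(NULL)
    data.frame(lap = l, width_cm = (max(nz) - min(nz) + 1L) * bw)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(lap = integer(0), width_cm = numeric(0),
                      width_norm = numeric(0)))
  }
  out$width_norm <- out$width_cm / mean(out$width_cm)
  out
}

#' Out-of-field / in-field firing ratio
#'
#' Ratio of the mean \eqn{\Delta}F/F in bins outside the field to the mean
#' inside, over all laps of the unmasked matrix.
#'
#' @param matrix unmasked lap-by-bin matrix (out-of-field activity retained).
#' @param field one-row data.frame with `bin_start`, `bin_end`.
#' @return The ratio (unitless).
#' @export
out_in_ratio <- function(matrix, field) {
  cols <- field$bin_start:field$bin_end
  in_mean <- mean(matrix[, cols])
  if (in_mean == 0) stop("zero in-field mean; ratio undefined")
  if (length(cols) == ncol(matrix)) return(0)
  mean(matrix[, -cols]) / in_mean
}

#' Place-field onset lap
#'
#' Scanning from lap 1: at the first lap with an in-field transient, examine
#' that lap plus the next `window - 1`; if at least `rule` of those laps have
#' in-field transients, that lap is the onset lap, otherwise the scan
#' continues from the next lap. Laps beyond the session end count as
#' inactive. `rule = 2` and `rule = 4` give the robustness variants.
#'
#' @param active_laps logical vector: laps with a significant in-field
#'   transient.
#' @param rule required active laps within the window (default 3).
#' @param window window length in laps (default 6).
#' @return The onset lap (1-based), or `NA_integer_` when no lap qualifies.
#' @export
onset_lap <- function(active_laps, rule = 3, window = 6) {
  n <- length(active_laps)
  for (l in seq_len(n)) {
    if (!active_laps[l]) next
    win <- l:min(l + window - 1L, n)
    if (sum(active_laps[win]) >= rule) return(l)
  }
  NA_integer_
}
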