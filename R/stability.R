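#' Spatial correlation of two activity maps
#'
#' Pearson's correlation coefficient between two mean activity maps along
#' the track (50 bins by default). Zero-variance maps are undefined.
#'
#' @param map_a,map_b mean \eqn{\Delta}F/F per bin, equal lengths.
#' @return Pearson r, or `NA` with a warning when a map has zero variance.
#' @export
spatial_correlation <- function(map_a, map_b) {
  stopifnot(length(map_a) == length(map_b))
  if (sd(map_a) == 0 || sd(map_b) == 0) {
    warning("zero-variance map; spatial correlation undefined")
    return(NA_real_)
  }
  cor(map_a, map_b)
}

#' Within-session map stability
#'
#' Correlates a cell's mean activity map between two parts of a session:
#' either the first 10 laps versus the next 10 (`"ten_laps"`) or the first
#' versus the second half of laps (`"halves"`).
#'
#' @param matrix lap-by-bin matrix.
#' @param mode `"ten_laps"` or `"halves"`.
#' @param n_laps_window laps per window in `"ten_laps"` mode.
#' @return Pearson r; `NA` when there are too few laps or a flat half-map.
#' @export
within_session_stability <- function(matrix, mode = c("ten_laps", "halves"),
                                     n_laps_window = 10) {
  mode <- match.arg(mode)
  nl <- nrow(matrix)
  if (mode == "ten_laps") {
    if (nl < 2 * n_laps_window) return(NA_real_)
    a <- colMeans(matrix[seq_len(n_laps_window), , drop = FALSE])
    b <- colMeans(matrix[n_laps_window + seq_len(n_laps_window), ,
                         drop = FALSE])
  } else {
    if (nl < 2) return(NA_real_)
    half <- floor(nl / 2)
    a <- colMeans(matrix[seq_len(half), , drop = FALSE])
    b <- colMeans(matrix[(half + 1):nl, , drop = FALSE])
  }
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Across-day map stability and classification
#'
#' Correlates the mean map of the last `n_laps` laps of day 1 with the first
#' `n_laps` laps of day 2 for the same cell, and classifies the field as
#' stable when r exceeds `stable_r` (exactly `stable_r` counts as unstable).
#'
#' @param day1_matrix,day2_matrix lap-by-bin matrices of the registered cell.
#' @param n_laps laps per window.
#' @param stable_r stability threshold on r.
#' @return A list: `r`, `stable` (`NA` when r is undefined).
#' @export
across_day_stability <- function(day1_matrix, day2_matrix, n_laps = 10,
                                 stable_r = 0.5) {
  nl1 <- nrow(day1_matrix); nl2 <- nrow(day2_matrix)
  a <- colMeans(day1_matrix[seq(max(1, nl1 - n_laps + 1), nl1), ,
                            drop = FALSE])
  b <- colMeans(day2_matrix[seq_len(min(n_laps, nl2)), , drop = FALSE])
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(r = NA_real_, stable = NA))
  }
  r <- cor(a, b)
  list(r = r, stable = r > stable_r)
}

#' Onset laps of stable versus newly formed day-2 fields
#'
#' Compares the day-2 onset-lap distributions of fields classified as stable
#' across days (re-emergence of a retrieved field) against newly formed
#' fields (unstable day-1 fields plus first-appearing fields), with a
#' two-sided rank-sum test.
#'
#' @param onsets_stable,onsets_new day-2 onset laps per class.
#' @return A list: `stable`, `new` (the onset vectors), `p_value` (rank-sum,
#'   `NA` when a class has fewer than 2 fields), and `ecdf_stable`,
#'   `ecdf_new`.
#' @export
stable_vs_new_onsets <- function(onsets_stable, onsets_new) {
  onsets_stable <- onsets_stable[!is.na(onsets_stable)]
  onsets_new <- onsets_new[!is.na(onsets_new)]
  p <- if (length(onsets_stable) >= 2 && length(onsets_new) >= 2) {
    suppressWarnings(wilcox.test(onsets_stable, onsets_new)$p.value)
  } else NA_real_
  list(stable = onsets_stable, new = onsets_new, p_value = p,
       ecdf_stable = stats::ecdf(onsets_stable),
       ecdf_new = stats::ecdf(onsets_new))
}
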