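#' Bootstrapped mean difference with percentile confidence interval
#'
#' Estimation-statistics contrast between two samples: the mean difference
#' mean(b) - mean(a) with a 95\% percentile bootstrap confidence interval,
#' resampling each group with replacement.
#'
#' @param a,b numeric samples (non-empty).
#' @param n_boot bootstrap resamples (default 5000; < 1000 warns).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return An object of class `"pf_estimation"`: `delta`, `ci_low`,
#'   `ci_high`, `boot` (the resampled differences), `n_boot`, `seed`.
#' @export
bootstrap_mean_difference <- function(a, b, n_boot = 5000, seed = 1L,
                                      conf = 0.95) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (n_boot < 1000) warning("n_boot < 1000 gives unstable intervals")
  set.seed(seed)
  na <- length(a); nb <- length(b)
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(b[sample.int(nb, nb, replace = TRUE)]) -
      mean(a[sample.int(na, na, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  structure(list(delta = mean(b) - mean(a), ci_low = ci[1], ci_high = ci[2],
                 boot = boot, n_boot = n_boot, seed = seed, conf = conf),
            class = "pf_estimation")
}

#' @export
print.pf_estimation <- function(x, ...) {
  cat(sprintf("mean difference %.4g [%.4g, %.4g] (%g%% percentile bootstrap, %d resamples)\n",
              x$delta, x$ci_low, x$ci_high, 100 * x$conf, x$n_boot))
  invisible(x)
}

#' Rank-based two-sample tests
#'
#' Thin wrapper dispatching to the Wilcoxon rank-sum, Wilcoxon signed-rank
#' (paired), or two-sample Kolmogorov-Smirnov test, two-sided.
#'
#' @param a,b numeric samples; `paired = TRUE` requires equal lengths.
#' @param test `"ranksum"`, `"signrank"` or `"ks"`.
#' @param paired use the signed-rank test on paired differences.
#' @return The two-sided p-value.
#' @export
rank_tests <- function(a, b, test = c("ranksum", "signrank", "ks"),
                       paired = FALSE) {
  test <- match.arg(test)
  if (length(a) == 0 || length(b) == 0) stop("zero-length sample")
  if (paired || test == "signrank") {
    stopifnot(length(a) == length(b))
    return(suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value))
  }
  switch(test,
         ranksum = suppressWarnings(wilcox.test(a, b)$p.value),
         ks = suppressWarnings(ks.test(a, b)$p.value))
}
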