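# Matched-pairs t-test power analysis via the noncentral t distribution.

#' Pooled standardized effect size from two mean +/- SD summaries
#'
#' `dz = |mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)`, the construction used
#' when sizing a matched-pairs comparison from two published summary
#' statistics.
#'
#' @param mean1,sd1 First method's mean and SD.
#' @param mean2,sd2 Second method's mean and SD.
#' @return Non-negative effect size dz.
#' @export
#' @examples pooled_effect_size(123, 28, 87, 14)  # ~1.63
pooled_effect_size <- function(mean1, sd1, mean2, sd2) {
  if (any(c(sd1, sd2) <= 0) || any(!is.finite(c(mean1, sd1, mean2, sd2)))) {
    stop_config("standard deviations must be positive and finite")
  }
  abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Power of a matched-pairs t test
#'
#' Exact power via the noncentral t distribution: with `df = n - 1`,
#' noncentrality `dz * sqrt(n)` and critical value
#' `t_crit = qt(1 - alpha/tails, df)`, power is
#' `P(T' > t_crit) + P(T' < -t_crit)` for a two-tailed test (the lower-tail
#' rejection contribution is included even though it is negligible at
#' moderate effect sizes).
#'
#' @param n Number of pairs (>= 2).
#' @param dz Standardized effect size of the paired differences.
#' @param alpha Type-I error probability (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Power in (0, 1).
#' @export
#' @examples paired_t_power(7, 1.63)  # >= 0.95
paired_t_power <- function(n, dz, alpha = 0.05, tails = 2) {
  stopifnot(tails %in% c(1, 2), alpha > 0, alpha < 1)
  if (any(n < 2)) stop_config("paired_t_power requires n >= 2")
  df <- n - 1
  ncp <- dz * sqrt(n)
  tcrit <- stats::qt(1 - alpha / tails, df)
  pow <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) pow <- pow + stats::pt(-tcrit, df, ncp = ncp)
  pow
}

#' Minimum sample size for a matched-pairs t test
#'
#' Smallest integer n with `paired_t_power(n, dz, alpha, tails) >= power`.
#'
#' @inheritParams paired_t_power
#' @param power Target power (default 0.95); must exceed `alpha`.
#' @param n_max Search ceiling (guards against dz ~ 0).
#' @return Integer sample size.
#' @export
#' @examples min_sample_size(1.63)  # 7
min_sample_size <- function(dz, alpha = 0.05, power = 0.95, tails = 2,
                            n_max = 1e6) {
  if (!is.finite(dz) || dz <= 0) stop_config("dz must be positive")
  stopifnot(alpha > 0, alpha < power, power < 1)
  n <- 2
  while (n <= n_max) {
    if (paired_t_power(n, dz, alpha, tails) >= power) return(as.integer(n))
    n <- n + 1
  }
  stop_config("no n <= %g reaches power %.3f at dz = %g", n_max, power, dz)
}
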