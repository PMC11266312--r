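# Validation metrics, Bland-Altman agreement, and rank aggregation.
#
# Each candidate formula is scored against the reference SV on four metrics:
# Pearson r, Hedges g (bias-corrected standardized mean difference), the sum
# of squared residuals SSR = sum((observed - predicted)^2), and the signed
# mean bias. Per-metric competition ranks (|r| descending; |g|, SSR, |bias|
# ascending; ties share the minimum rank) are summed into a total score; the
# formula with the smallest total wins.

#' Pearson product-moment correlation
#'
#' Thin, argument-checked wrapper around [stats::cor()] that signals (rather
#' than silently NA-ing) constant series, which downstream ranking treats as
#' an undefined metric (ranked last).
#'
#' @param x,y Aligned numeric vectors, n >= 3.
#' @return Correlation in `[-1, 1]`, or `NA_real_` (with a warning) when a
#'   series is constant.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop_config("pearson_r needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("undefined correlation: constant series", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Hedges g standardized mean difference
#'
#' `g = |mean(x) - mean(y)| / s_pooled * J` with
#' `s_pooled = sqrt((sd_x^2 + sd_y^2) / 2)` and the small-sample correction
#' `J = 1 - 3 / (4 (2n - 2) - 1)`. Reported as a positive magnitude.
#'
#' @param x,y Aligned numeric vectors (equal length n >= 2).
#' @param correction `TRUE` (Hedges g, default) or `FALSE` (uncorrected
#'   Cohen d with the same pooled-SD construction).
#' @return Non-negative effect size; `Inf` (with warning) when the pooled SD
#'   is zero but the means differ; 0 when both are zero.
#' @export
#' @examples hedges_g(c(1, 2, 3), c(1, 2, 3))  # 0
hedges_g <- function(x, y, correction = TRUE) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  s_pooled <- sqrt((stats::sd(x)^2 + stats::sd(y)^2) / 2)
  delta <- abs(mean(x) - mean(y))
  if (s_pooled == 0) {
    if (delta == 0) return(0)
    warning("zero pooled SD with unequal means: infinite effect size",
            call. = FALSE)
    return(Inf)
  }
  J <- if (correction) 1 - 3 / (4 * (2 * n - 2) - 1) else 1
  delta / s_pooled * J
}

#' Sum of squared residuals
#'
#' The residual is observed minus predicted; `ssr = sum((x - y)^2)` (mL^2).
#' Note SSR is a raw sum, so comparisons across formulae are only meaningful
#' on the identical record set.
#'
#' @param x Observed (measured) SV. @param y Predicted SV, aligned.
#' @export
sum_squared_residuals <- function(x, y) {
  stopifnot(length(x) == length(y))
  sum((x - y)^2)
}

#' Mean bias
#'
#' Signed mean of observed minus predicted (mL). Ranking consumes `|bias|`.
#'
#' @param x Observed SV. @param y Predicted SV, aligned.
#' @export
mean_bias <- function(x, y) {
  stopifnot(length(x) == length(y))
  mean(x - y)
}

#' Bland-Altman limits of agreement
#'
#' Bias (mean difference), sample SD of the differences, and the 95% limits
#' of agreement `bias +/- 1.96 * sd_diff`.
#'
#' @param x,y Aligned paired measurements (n >= 3).
#' @return A `sv_bland_altman` list: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `level` (0.95), plus the differences and pair means for
#'   plotting.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop_config("bland_altman needs at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 level = 0.95, differences = d, means = (x + y) / 2),
            class = "sv_bland_altman")
}

#' @export
print.sv_bland_altman <- function(x, ...) {
  cat(sprintf("<Bland-Altman> bias %.2f mL, SD of differences %.2f mL, 95%% LoA [%.2f, %.2f]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Limits of agreement around a reference stroke volume
#'
#' Projects the Bland-Altman limits onto a reference SV: a subject whose true
#' SV is `reference_mean` is expected to be *estimated* within
#' `reference_mean - loa_high` to `reference_mean - loa_low` mL (since the
#' difference is observed minus predicted). The same interval is also
#' returned as a percentage of the reference. This relative form is one
#' possible reading of an agreement "coefficient of variation"; it is
#' provided as an explicitly labelled interpretation, not a standard
#' quantity.
#'
#' @param ba A [bland_altman()] result. @param reference_mean Reference SV, mL.
#' @return Named vector: `low_ml`, `high_ml` (predicted-SV interval, mL) and
#'   `low_pct`, `high_pct` (same interval as % of `reference_mean`).
#' @export
loa_cv_ratio <- function(ba, reference_mean) {
  stopifnot(inherits(ba, "sv_bland_altman"), reference_mean > 0)
  low <- reference_mean - ba$loa_high
  high <- reference_mean - ba$loa_low
  c(low_ml = low, high_ml = high,
    low_pct = low / reference_mean * 100,
    high_pct = high / reference_mean * 100)
}

#' Compute the four validation metrics for one paired series
#'
#' @param pair A pairing from [pair_series()], or a list with `x`, `y` (and
#'   optionally `formula_id`, `stratum`).
#' @param effect_size `"hedges"` (default) or `"cohen"`.
#' @return One-row data.frame (`sv_metric_set`): `formula_id`, `stratum`,
#'   `n`, `r`, `g`, `ssr`, `bias`, `mean_measured`, `sd_measured`,
#'   `mean_predicted`, `sd_predicted`.
#' @export
compute_metrics <- function(pair, effect_size = c("hedges", "cohen")) {
  effect_size <- match.arg(effect_size)
  x <- pair$x; y <- pair$y
  n <- length(x)
  strat_label <- if (!is.null(pair$stratum)) format(pair$stratum) else "both/both"
  if (n < 3L) {
    return(data.frame(formula_id = pair$formula_id %||% NA_character_,
                      stratum = strat_label, n = n, r = NA_real_, g = NA_real_,
                      ssr = NA_real_, bias = NA_real_,
                      mean_measured = if (n) mean(x) else NA_real_,
                      sd_measured = NA_real_, mean_predicted = if (n) mean(y) else NA_real_,
                      sd_predicted = NA_real_, stringsAsFactors = FALSE))
  }
  r <- suppressWarnings(pearson_r(x, y))
  data.frame(formula_id = pair$formula_id %||% NA_character_,
             stratum = strat_label, n = n, r = r,
             g = suppressWarnings(hedges_g(x, y, correction = effect_size == "hedges")),
             ssr = sum_squared_residuals(x, y), bias = mean_bias(x, y),
             mean_measured = mean(x), sd_measured = stats::sd(x),
             mean_predicted = mean(y), sd_predicted = stats::sd(y),
             stringsAsFactors = FALSE)
}

# competition ranking: best value gets rank 1, ties share the minimum rank,
# undefined metrics (NA/Inf on an ascending scale) are ranked last.
competition_rank <- function(values, decreasing = FALSE) {
  v <- if (decreasing) -values else values
  v[!is.finite(v)] <- Inf
  r <- rep(NA_integer_, length(v))
  o <- order(v)
  sorted <- v[o]
  rk <- integer(length(v))
  for (i in seq_along(sorted)) {
    rk[i] <- if (i > 1L && sorted[i] == sorted[i - 1L]) rk[i - 1L] else i
  }
  r[o] <- rk
  r
}

#' Aggregate per-metric ranks into a total score
#'
#' Ranks every formula on each of the four metrics (|r| descending, |g|
#' ascending, SSR ascending, |bias| ascending), using competition ranking
#' (ties share the minimum rank), sums the four ranks into `total_score`,
#' and orders final positions by ascending total. Undefined metrics are
#' ranked last and flagged in `note`.
#'
#' @param metric_sets data.frame of metric rows (one per formula, same
#'   stratum), e.g. `rbind()` of [compute_metrics()] outputs.
#' @return `sv_ranking_table` data.frame: metrics plus `rank_r`, `rank_g`,
#'   `rank_ssr`, `rank_bias`, `total_score`, `final_position`, `note`,
#'   ordered by `final_position`.
#' @export
rank_formulae <- function(metric_sets) {
  stopifnot(is.data.frame(metric_sets), nrow(metric_sets) >= 2L)
  ms <- metric_sets
  ms$rank_r <- competition_rank(abs(ms$r), decreasing = TRUE)
  ms$rank_g <- competition_rank(abs(ms$g))
  ms$rank_ssr <- competition_rank(ms$ssr)
  ms$rank_bias <- competition_rank(abs(ms$bias))
  ms$total_score <- ms$rank_r + ms$rank_g + ms$rank_ssr + ms$rank_bias
  ms$final_position <- competition_rank(ms$total_score)
  undef <- !is.finite(ms$r) | !is.finite(ms$g) | !is.finite(ms$ssr) |
    !is.finite(ms$bias)
  ms$note <- ifelse(undef, "undefined metric(s): ranked last", "")
  ms <- ms[order(ms$final_position, ms$formula_id), , drop = FALSE]
  rownames(ms) <- NULL
  class(ms) <- c("sv_ranking_table", "data.frame")
  ms
}

#' Evaluate all formulae on one stratum
#'
#' Pairs each formula's predictions with the measured SV in `strat` and
#' computes the metric set; formulae with fewer than 3 applicable pairs in
#' the stratum are dropped with a warning (empty-stratum signal).
#'
#' @param records Cleaned observation data.frame.
#' @param subjects Subject profiles.
#' @param strat Analysis [stratum()].
#' @param registry,vf_table,lu_extra See [predict_records()].
#' @param effect_size See [compute_metrics()].
#' @param predictions Optional precomputed [predict_records()] table for
#'   `records` (avoids recomputation across strata).
#' @return Ranking table from [rank_formulae()].
#' @export
evaluate_formulae <- function(records, subjects, strat = stratum(),
                              registry = sv_registry(), vf_table = NULL,
                              lu_extra = "constant",
                              effect_size = "hedges", predictions = NULL) {
  if (is.null(predictions)) {
    predictions <- predict_records(records, subjects, registry = registry,
                                   vf_table = vf_table, lu_extra = lu_extra)
  }
  rows <- lapply(names(registry), function(id) {
    pr <- pair_series(records, predictions, id, strat)
    if (pr$n < 3L) return(NULL)
    compute_metrics(pr, effect_size = effect_size)
  })
  dropped <- names(registry)[vapply(rows, is.null, TRUE)]
  if (length(dropped)) {
    warning(sprintf("dropped formula(e) with < 3 applicable pairs in stratum %s: %s",
                    format(strat), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  ms <- do.call(rbind, rows)
  rank_formulae(ms)
}

#' Stratified ranking report over the nine posture x condition cells
#'
#' Runs [evaluate_formulae()] for each requested stratum and summarizes the
#' winning formula per cell (lowest total score) together with its metric
#' set, mirroring a best-formula-per-condition table. Empty strata are
#' omitted with a warning.
#'
#' @inheritParams evaluate_formulae
#' @param strata List of [stratum()] objects (default: all nine).
#' @return `list(rankings = named list of ranking tables, best = data.frame
#'   of per-stratum winners)`.
#' @export
stratified_report <- function(records, subjects, strata = all_strata(),
                              registry = sv_registry(), vf_table = NULL,
                              lu_extra = "constant", effect_size = "hedges") {
  predictions <- predict_records(records, subjects, registry = registry,
                                 vf_table = vf_table, lu_extra = lu_extra)
  rankings <- list()
  best <- list()
  for (strat in strata) {
    label <- format(strat)
    sub_n <- nrow(filter_stratum(records, strat))
    if (sub_n < 3L) {
      warning(sprintf("stratum %s has %d records: omitted", label, sub_n),
              call. = FALSE)
      next
    }
    tab <- evaluate_formulae(records, subjects, strat, registry = registry,
                             vf_table = vf_table, lu_extra = lu_extra,
                             effect_size = effect_size,
                             predictions = predictions)
    rankings[[label]] <- tab
    best[[label]] <- tab[1L, , drop = FALSE]
  }
  best <- do.call(rbind, best)
  rownames(best) <- NULL
  list(rankings = rankings, best = best)
}
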