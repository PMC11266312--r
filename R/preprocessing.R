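# Data-integrity filters and measured/predicted pairing.
#
# The cleaning protocol is fixed: (1) drop beats whose measured SV lies
# outside the plausible 61-145 mL window (movement artefact), then (2) drop
# beats whose SAP or DAP deviates from its group mean by more than k = 2
# sample SDs, with group statistics computed once on the post-step-1 data
# (no iterative re-screening). Permuting the two steps can change the result,
# so only this order is offered.

cleaning_report <- function(n_input, n_sv, n_bp, grouping = NA_character_) {
  stopifnot(n_input == n_sv + n_bp + (n_input - n_sv - n_bp))
  structure(list(n_input = n_input,
                 n_removed_sv_range = n_sv,
                 n_removed_bp_outlier = n_bp,
                 n_retained = n_input - n_sv - n_bp,
                 grouping_used = grouping),
            class = "sv_cleaning_report")
}

#' @export
print.sv_cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("<cleaning report> %d records in; %d removed by SV range,",
                     " %d by BP outlier screen (grouping: %s); %d retained\n"),
              x$n_input, x$n_removed_sv_range, x$n_removed_bp_outlier,
              x$grouping_used, x$n_retained))
  invisible(x)
}

#' Filter physiologically implausible stroke volumes
#'
#' Removes records whose measured SV falls outside `[low, high]` mL
#' (inclusive at both ends); such beats are attributed to movement artefact.
#'
#' @param records Observation data.frame with an `sv_measured` column (mL).
#' @param low,high Plausibility window bounds, mL (defaults 61 and 145).
#' @return `list(records = retained data.frame, report = cleaning report)`.
#' @export
#' @examples
#' recs <- data.frame(sv_measured = c(60.9, 61, 100, 145, 145.1))
#' filter_sv_plausibility(recs)$records$sv_measured  # 61 100 145
filter_sv_plausibility <- function(records, low = 61, high = 145) {
  stopifnot(low < high)
  if (nrow(records) == 0L) {
    return(list(records = records, report = cleaning_report(0L, 0L, 0L)))
  }
  keep <- records$sv_measured >= low & records$sv_measured <= high
  keep[is.na(keep)] <- FALSE
  list(records = records[keep, , drop = FALSE],
       report = cleaning_report(nrow(records), sum(!keep), 0L))
}

bp_group_key <- function(records, grouping) {
  switch(grouping,
         global = rep("all", nrow(records)),
         per_subject = as.character(records$subject_id),
         per_subject_stratum = paste(records$subject_id, records$posture,
                                     records$condition, sep = "\r"),
         stop_config("unknown BP outlier grouping '%s'", grouping))
}

#' Screen blood-pressure outliers at k standard deviations
#'
#' Removes a record when its SAP *or* DAP deviates from the group mean by
#' more than `k` sample standard deviations. Group means/SDs are computed
#' once on the input (single pass; removals do not trigger re-computation).
#' Groups with fewer than 3 records are passed through untouched (and noted
#' in a message), since a 2-SD screen is meaningless there.
#'
#' @param records Observation data.frame with `sap` and `dap` columns (mmHg).
#' @param k Deviation threshold in SD units (default 2; `Inf` disables).
#' @param grouping `"per_subject_stratum"` (default; subject x posture x
#'   condition), `"per_subject"`, or `"global"`. Postural/thermal BP shifts
#'   would be purged as outliers under coarser groupings, hence the default.
#' @return `list(records, report)` as in [filter_sv_plausibility()].
#' @export
filter_bp_outliers <- function(records, k = 2,
                               grouping = c("per_subject_stratum",
                                            "per_subject", "global")) {
  grouping <- match.arg(grouping)
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  if (nrow(records) == 0L) {
    return(list(records = records,
                report = cleaning_report(0L, 0L, 0L, grouping)))
  }
  key <- bp_group_key(records, grouping)
  remove <- rep(FALSE, nrow(records))
  small <- 0L
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) < 3L) { small <- small + 1L; next }
    for (col in c("sap", "dap")) {
      v <- records[[col]][idx]
      s <- stats::sd(v)                       # sample SD, n-1 denominator
      if (!is.finite(s) || s == 0) next
      remove[idx] <- remove[idx] | abs(v - mean(v)) > k * s
    }
  }
  if (small > 0L) {
    message(sprintf("filter_bp_outliers: %d group(s) with < 3 records passed through unscreened", small))
  }
  list(records = records[!remove, , drop = FALSE],
       report = cleaning_report(nrow(records), 0L, sum(remove), grouping))
}

#' Apply the full cleaning protocol
#'
#' SV plausibility window first, then the BP outlier screen, with one
#' combined report. Every input record lands in exactly one of
#' retained / removed-by-SV / removed-by-BP.
#'
#' @inheritParams filter_sv_plausibility
#' @inheritParams filter_bp_outliers
#' @return `list(records, report)`.
#' @export
clean_records <- function(records, low = 61, high = 145, k = 2,
                          grouping = "per_subject_stratum") {
  s1 <- filter_sv_plausibility(records, low = low, high = high)
  s2 <- filter_bp_outliers(s1$records, k = k, grouping = grouping)
  list(records = s2$records,
       report = cleaning_report(s1$report$n_input,
                                s1$report$n_removed_sv_range,
                                s2$report$n_removed_bp_outlier,
                                grouping))
}

#' Posture/condition analysis stratum
#'
#' The analysis grid crosses posture (supine, 60 degree head-up tilt, both)
#' with ambient condition (thermoneutral, hot, both), giving nine cells.
#'
#' @param posture `"supine"`, `"hut60"`, or `"both"`.
#' @param condition `"thermoneutral"`, `"hot"`, or `"both"`.
#' @return An `sv_stratum` object.
#' @export
stratum <- function(posture = c("both", "supine", "hut60"),
                    condition = c("both", "thermoneutral", "hot")) {
  structure(list(posture = match.arg(posture),
                 condition = match.arg(condition)),
            class = "sv_stratum")
}

#' @export
print.sv_stratum <- function(x, ...) {
  cat(sprintf("<stratum> posture = %s, condition = %s\n", x$posture, x$condition))
  invisible(x)
}

#' @export
format.sv_stratum <- function(x, ...) {
  paste0(x$posture, "/", x$condition)
}

#' All nine analysis strata
#' @return List of nine [stratum()] objects (both/both first).
#' @export
all_strata <- function() {
  cells <- expand.grid(posture = c("both", "supine", "hut60"),
                       condition = c("both", "thermoneutral", "hot"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    stratum(cells$posture[i], cells$condition[i])
  })
}

#' Subset records to one stratum
#' @param records Observation data.frame. @param strat An [stratum()].
#' @return The matching subset.
#' @export
filter_stratum <- function(records, strat) {
  keep <- rep(TRUE, nrow(records))
  if (strat$posture != "both") keep <- keep & records$posture == strat$posture
  if (strat$condition != "both") keep <- keep & records$condition == strat$condition
  records[keep, , drop = FALSE]
}

#' Pair measured and predicted series for one formula in one stratum
#'
#' Aligns measured SV with one formula's predictions by record identity,
#' keeping only applicable predictions; records a formula skips (e.g. BMI
#' above the de Simone limit) reduce n for that formula only.
#'
#' @param records Cleaned observation data.frame.
#' @param predictions Long prediction table from [predict_records()] computed
#'   on the same `records` (its `.row` indexes `records`).
#' @param formula_id Which formula to pair.
#' @param strat Analysis [stratum()] (default: all data).
#' @return `list(x = measured SV, y = predicted SV, n, formula_id, stratum)`;
#'   `n = 0` signals an empty stratum for downstream handling.
#' @export
pair_series <- function(records, predictions, formula_id, strat = stratum()) {
  pred <- predictions[predictions$formula_id == formula_id, , drop = FALSE]
  if (nrow(pred) != nrow(records)) {
    stop_config("predictions for '%s' do not align with records (%d vs %d rows)",
                formula_id, nrow(pred), nrow(records))
  }
  pred <- pred[order(pred$.row), , drop = FALSE]
  keep <- rep(TRUE, nrow(records))
  if (strat$posture != "both") keep <- keep & records$posture == strat$posture
  if (strat$condition != "both") keep <- keep & records$condition == strat$condition
  keep <- keep & pred$applicable
  list(x = records$sv_measured[keep], y = pred$sv_predicted[keep],
       n = sum(keep), formula_id = formula_id, stratum = strat)
}
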