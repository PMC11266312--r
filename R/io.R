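# CSV/JSON I/O and the end-to-end pipeline driver.
#
# Canonical observation CSV dialect: comma-separated, UTF-8, "." decimal,
# header required, columns subject_id, day, posture, condition, sap_mmhg,
# dap_mmhg, hr_bpm, sv_ml; posture in {supine, hut60}, condition in
# {thermoneutral, hot} (case-insensitive on read, canonical lower-case on
# write).

obs_csv_cols <- c(subject_id = "subject_id", day = "day", posture = "posture",
                  condition = "condition", sap = "sap_mmhg", dap = "dap_mmhg",
                  hr = "hr_bpm", sv_measured = "sv_ml")

normalize_label <- function(x, valid, what, allow = character()) {
  lx <- tolower(trimws(x))
  lx[lx %in% names(allow)] <- allow[lx[lx %in% names(allow)]]
  bad <- !lx %in% valid
  if (any(bad)) {
    stop_config("unknown %s label(s) in row(s) %s: %s", what,
                paste(utils::head(which(bad), 5L), collapse = ", "),
                paste(unique(x[bad]), collapse = ", "))
  }
  lx
}

#' Validate an observation table
#'
#' Checks the record invariants (`sap > dap > 0`, positive SV, HR in
#' (20, 250) when present) and reports offending row indices.
#'
#' @param records Observation data.frame (internal column names).
#' @return The records, invisibly, or an error listing offending rows.
#' @export
validate_observations <- function(records) {
  num <- c("sap", "dap", "sv_measured")
  for (col in num) {
    if (any(!is.finite(records[[col]]))) {
      stop_config("non-numeric or missing %s in row(s): %s", col,
                  paste(utils::head(which(!is.finite(records[[col]])), 5L),
                        collapse = ", "))
    }
  }
  bad <- records$dap <= 0 | records$sap <= records$dap
  if (any(bad)) {
    stop_config("pressure invariant sap > dap > 0 violated in row(s): %s",
                paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (any(records$sv_measured <= 0)) {
    stop_config("non-positive measured SV in row(s): %s",
                paste(utils::head(which(records$sv_measured <= 0), 5L),
                      collapse = ", "))
  }
  if (!is.null(records$hr)) {
    badhr <- is.finite(records$hr) & (records$hr <= 20 | records$hr >= 250)
    if (any(badhr)) {
      stop_config("heart rate outside (20, 250) bpm in row(s): %s",
                  paste(utils::head(which(badhr), 5L), collapse = ", "))
    }
  }
  invisible(records)
}

#' Read / write observation CSV
#'
#' @param path CSV file path.
#' @return `read_observations()`: validated observation data.frame with
#'   internal column names (`sap`, `dap`, `hr`, `sv_measured`, ...).
#' @export
read_observations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(obs_csv_cols), names(raw))
  if (length(missing)) {
    stop_config("observation CSV %s is missing column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  out <- data.frame(
    subject_id = as.character(raw$subject_id),
    day = as.integer(raw$day),
    posture = normalize_label(raw$posture, c("supine", "hut60"), "posture",
                              allow = c("hut" = "hut60", "tilt" = "hut60")),
    condition = normalize_label(raw$condition, c("thermoneutral", "hot"),
                                "condition",
                                allow = c("neutral" = "thermoneutral",
                                          "heatwave" = "hot")),
    sap = as.numeric(raw$sap_mmhg), dap = as.numeric(raw$dap_mmhg),
    hr = as.numeric(raw$hr_bpm), sv_measured = as.numeric(raw$sv_ml),
    stringsAsFactors = FALSE)
  validate_observations(out)
  out
}

#' @rdname read_observations
#' @param records Observation data.frame to write.
#' @export
write_observations <- function(records, path) {
  out <- data.frame(subject_id = records$subject_id, day = records$day,
                    posture = records$posture, condition = records$condition,
                    sap_mmhg = records$sap, dap_mmhg = records$dap,
                    hr_bpm = records$hr, sv_ml = records$sv_measured)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write participant anthropometry CSV
#'
#' Columns: `subject_id, age_yr, height_m, weight_kg`; BSA and BMI are
#' derived on read.
#'
#' @param path CSV path. @param bsa_method See [derive_bsa()].
#' @export
read_participants <- function(path, bsa_method = "dubois") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_yr", "height_m", "weight_kg")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop_config("participant CSV %s is missing column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  subject_profile(raw$subject_id, raw$age_yr, raw$height_m, raw$weight_kg,
                  bsa_method = bsa_method)
}

#' @rdname read_participants
#' @param participants Subject profile data.frame to write.
#' @export
write_participants <- function(participants, path) {
  out <- data.frame(subject_id = participants$subject_id,
                    age_yr = participants$age, height_m = participants$height,
                    weight_kg = participants$weight)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a ranking table as CSV / a stratified report as JSON
#'
#' @param table An [rank_formulae()] table. @param path Output path.
#' @param registry Registry used to attach labels and equation strings.
#' @export
write_ranking <- function(table, path, registry = sv_registry()) {
  idx <- match(table$formula_id, names(registry))
  out <- cbind(
    label = vapply(registry[idx], `[[`, "", "label"),
    equation = vapply(registry[idx], `[[`, "", "equation"),
    as.data.frame(table))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @param report A [stratified_report()] result.
#' @export
write_report <- function(report, path) {
  payload <- list(
    best = report$best,
    rankings = lapply(report$rankings, function(t) as.data.frame(t)))
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bland-Altman agreement plot
#'
#' Differences (measured - predicted) against pair means, with the bias line
#' (solid), +/- 1 SD (fine dashed) and the 95% limits of agreement (thick
#' dashed).
#'
#' @param ba A [bland_altman()] result.
#' @param main Plot title.
#' @param file Optional PNG path; when given, the plot is written there
#'   instead of the active device.
#' @export
plot_bland_altman <- function(ba, main = "Bland-Altman agreement", file = NULL) {
  stopifnot(inherits(ba, "sv_bland_altman"))
  draw <- function() {
    graphics::plot(ba$means, ba$differences, pch = 16,
                   col = grDevices::adjustcolor("grey25", 0.6),
                   xlab = "Mean of measured and predicted SV (mL)",
                   ylab = "Measured - predicted SV (mL)", main = main,
                   ylim = range(ba$differences, ba$loa_low, ba$loa_high))
    graphics::abline(h = ba$bias, lwd = 2)
    graphics::abline(h = ba$bias + c(-1, 1) * ba$sd_diff, lty = 3,
                     col = "darkorange")
    graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2, lwd = 2,
                     col = "blue3")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 1400, height = 1000, res = 160)
    on.exit(grDevices::dev.off())
    draw()
    return(invisible(file))
  }
  draw()
  invisible(NULL)
}

#' Run the end-to-end validation pipeline
#'
#' Reads (or simulates) observations and participants, applies the cleaning
#' protocol, evaluates and ranks every registry formula per stratum, and
#' writes all artifacts into `output_dir`: the cleaned observation CSV, the
#' cleaning report (JSON), one ranking CSV per stratum, the stratified
#' summary (JSON), a Bland-Altman plot for the overall best formula, and a
#' log of the fully resolved configuration.
#'
#' @param observations Observation data.frame, or path to an observation CSV;
#'   `NULL` to simulate.
#' @param participants Subject profiles, or path to a participant CSV;
#'   `NULL` to simulate.
#' @param output_dir Output directory (created if absent). Input files are
#'   never modified.
#' @param seed Seed for the simulation branch.
#' @param bp_outlier_grouping,sv_range,bp_k Cleaning settings, see
#'   [clean_records()].
#' @param strata Strata to evaluate (default: all nine).
#' @param registry,vf_table,lu_extra,effect_size Evaluation settings.
#' @param protocol,model Generator settings for the simulation branch.
#' @return Invisibly, `list(report, cleaning, paths)`.
#' @export
run_pipeline <- function(observations = NULL, participants = NULL,
                         output_dir = "sv_run", seed = 1,
                         bp_outlier_grouping = "per_subject_stratum",
                         sv_range = c(61, 145), bp_k = 2,
                         strata = all_strata(), registry = sv_registry(),
                         vf_table = NULL, lu_extra = "constant",
                         effect_size = "hedges",
                         protocol = protocol_config(),
                         model = generator_model()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(observations)
  if (simulated) {
    sim <- simulate_study(protocol, model, seed = seed)
    observations <- sim$observations
    participants <- sim$participants
  } else {
    if (is.character(observations)) observations <- read_observations(observations)
    if (is.character(participants)) participants <- read_participants(participants)
    if (is.null(participants)) stop_config("participants required with observations")
  }
  validate_observations(observations)

  cleaned <- clean_records(observations, low = sv_range[1], high = sv_range[2],
                           k = bp_k, grouping = bp_outlier_grouping)
  paths <- list(
    cleaned_csv = file.path(output_dir, "observations_cleaned.csv"),
    cleaning_json = file.path(output_dir, "cleaning_report.json"),
    report_json = file.path(output_dir, "stratified_report.json"),
    bland_altman_png = file.path(output_dir, "bland_altman_best.png"),
    log = file.path(output_dir, "run_log.txt"))
  write_observations(cleaned$records, paths$cleaned_csv)
  jsonlite::write_json(unclass(cleaned$report), paths$cleaning_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- stratified_report(cleaned$records, participants, strata = strata,
                              registry = registry, vf_table = vf_table,
                              lu_extra = lu_extra, effect_size = effect_size)
  for (label in names(report$rankings)) {
    fname <- file.path(output_dir,
                       paste0("ranking_", gsub("/", "_", label), ".csv"))
    write_ranking(report$rankings[[label]], fname, registry = registry)
    paths[[paste0("ranking_", label)]] <- fname
  }
  write_report(report, paths$report_json)

  best_id <- report$best$formula_id[report$best$stratum == "both/both"]
  if (length(best_id) == 1L) {
    preds <- predict_records(cleaned$records, participants,
                             formula_ids = best_id, registry = registry,
                             vf_table = vf_table, lu_extra = lu_extra)
    pr <- pair_series(cleaned$records, preds, best_id)
    ba <- bland_altman(pr$x, pr$y)
    plot_bland_altman(ba, main = sprintf("Best formula (%s)", best_id),
                      file = paths$bland_altman_png)
  }

  log_lines <- c(
    sprintf("svformula %s | R %s", as.character(utils::packageVersion("svformula")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("input: %s", if (simulated) sprintf("simulated (seed %s)", seed)
            else "user-supplied"),
    sprintf("records in: %d; removed SV range: %d; removed BP outlier: %d; retained: %d",
            cleaned$report$n_input, cleaned$report$n_removed_sv_range,
            cleaned$report$n_removed_bp_outlier, cleaned$report$n_retained),
    sprintf("bp outlier grouping: %s; sv window: [%g, %g] mL; k = %g",
            bp_outlier_grouping, sv_range[1], sv_range[2], bp_k),
    sprintf("effect size: %s; lu term: %s; remington table: %s",
            effect_size, lu_extra, if (is.null(vf_table)) "absent" else "supplied"),
    vapply(names(report$rankings), function(l) {
      sprintf("stratum %s: n = %d, best = %s (total score %d)", l,
              report$rankings[[l]]$n[1], report$rankings[[l]]$formula_id[1],
              report$rankings[[l]]$total_score[1])
    }, ""))
  writeLines(log_lines, paths$log)
  invisible(list(report = report, cleaning = cleaned$report, paths = paths))
}
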