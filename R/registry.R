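# Formula registry: the 22 published stroke-volume prediction formulae,
# loaded from the versioned JSON shipped in inst/extdata.

registry_env <- new.env(parent = emptyenv())

#' The stroke-volume formula registry
#'
#' Loads (and caches) the registry of 22 published formulae that predict
#' stroke volume (SV, mL) from arterial pressure, age and/or anthropometry.
#' Entries are kept in their canonical presentation order and carry the
#' equation string as printed in the source literature, the interpreted
#' functional form and coefficients, required inputs, units, and
#' applicability constraints (e.g. the de Simone formulae apply only to
#' subjects with BMI <= 25.25 kg/m^2; the Remington aortic volume-factor
#' formula needs a user-supplied pressure-to-volume-factor table).
#'
#' @param path Optional path to an alternative registry JSON file.
#' @return A list of class `sv_registry`; each element is one formula entry.
#' @export
#' @examples
#' reg <- sv_registry()
#' length(reg)            # 22
#' formula_ids(reg)[1:3]
sv_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(registry_env$default)) return(registry_env$default)
    path <- system.file("extdata", "formula_registry.json", package = "svformula")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(raw$entries, function(e) {
    e$coef <- lapply(e$coef, as.numeric)
    e$required_inputs <- as.character(unlist(e$required_inputs))
    class(e) <- "sv_formula_spec"
    e
  })
  ids <- vapply(entries, `[[`, "", "formula_id")
  if (anyDuplicated(ids)) stop_config("duplicate formula_id in registry")
  if (length(entries) != 22L) {
    stop_config("registry must contain exactly 22 formulae, found %d", length(entries))
  }
  names(entries) <- ids
  structure(entries,
            class = "sv_registry",
            registry_version = raw$registry_version)
  }

#' @export
print.sv_registry <- function(x, ...) {
  cat(sprintf("<sv_registry> %d stroke-volume formulae (version %s)\n",
              length(x), attr(x, "registry_version")))
  for (e in x) cat(sprintf("  %-20s %s\n", e$formula_id, e$equation))
  invisible(x)
}

#' @export
print.sv_formula_spec <- function(x, ...) {
  cat(sprintf("<sv_formula_spec> %s\n  %s\n  printed: %s\n  inputs: %s\n",
              x$formula_id, x$label, x$equation,
              paste(x$required_inputs, collapse = ", ")))
  if (!is.null(x$interpretation)) cat("  interpreted as:", x$interpretation, "\n")
  invisible(x)
}

#' Formula identifiers in registry (presentation) order
#' @param registry A registry from [sv_registry()].
#' @return Character vector of 22 stable formula ids.
#' @export
formula_ids <- function(registry = sv_registry()) {
  unname(vapply(registry, `[[`, "", "formula_id"))
}

#' Look up one registry entry
#' @param formula_id Stable formula key, e.g. `"starr54_eq72"`.
#' @param registry A registry from [sv_registry()].
#' @export
formula_info <- function(formula_id, registry = sv_registry()) {
  if (!formula_id %in% names(registry)) {
    stop_config("unknown formula_id '%s'", formula_id)
  }
  registry[[formula_id]]
}

#' Canonical pressure-linear coefficients
#'
#' Every pressure-based formula in the registry reduces algebraically to the
#' canonical form `SV = a + b*PP - c*DAP - d*age`. This helper returns that
#' reduction (used e.g. to invert a generating formula in the synthetic-data
#' module), or `NULL` for anthropometric / HR-based / table-lookup formulae
#' that have no such form.
#'
#' @param formula_id Formula key or an `sv_formula_spec`.
#' @param registry A registry from [sv_registry()].
#' @return Named numeric vector `c(a, b, c, d)`, or `NULL`.
#' @export
canonical_coefficients <- function(formula_id, registry = sv_registry()) {
  e <- if (inherits(formula_id, "sv_formula_spec")) formula_id else
    formula_info(formula_id, registry)
  cf <- e$coef
  switch(e$form,
    starr_linear = c(a = cf$a, b = cf$b, c = cf$c, d = cf$d),
    jackson = c(a = cf$a, b = cf$b, c = cf$c - cf$b, d = cf$d),
    starr_bracket = c(a = cf$a, b = cf$b - cf$c * cf$k, c = cf$c, d = cf$d),
    scaled_starr = c(a = cf$s * cf$a + cf$t, b = cf$s * cf$b,
                     c = cf$s * cf$c, d = cf$s * cf$d),
    NULL)
}

#' Pulse pressure from systolic and diastolic pressure
#'
#' @param sap Systolic arterial pressure, mmHg.
#' @param dap Diastolic arterial pressure, mmHg. Recycled with `sap`.
#' @return Pulse pressure `sap - dap`, mmHg.
#' @export
#' @examples derive_pulse_pressure(120, 80)
derive_pulse_pressure <- function(sap, dap) {
  bad <- !is.finite(sap) | !is.finite(dap) | dap <= 0 | sap <= dap
  if (any(bad)) {
    stop_config(
      "invalid pressures: need sap > dap > 0 (offending record(s): %s)",
      paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  sap - dap
}

#' Body surface area from height and weight
#'
#' @param height_m Height in metres (converted to cm internally where the
#'   formula expects cm).
#' @param weight_kg Weight in kg.
#' @param method `"dubois"` (default): `0.007184 * cm^0.725 * kg^0.425`;
#'   `"mosteller"`: `sqrt(cm * kg / 3600)`.
#' @return BSA in m^2.
#' @export
#' @examples
#' derive_bsa(1.80, 81.5)               # ~2.01
#' derive_bsa(1.80, 81.5, "mosteller")  # ~2.02
derive_bsa <- function(height_m, weight_kg, method = c("dubois", "mosteller")) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("dubois", "mosteller")) {
    stop_config("unknown BSA method '%s' (use 'dubois' or 'mosteller')", method)
  }
  method <- match.arg(method)
  if (any(!is.finite(height_m) | height_m <= 1.0 | height_m >= 2.5)) {
    stop_config("height must be in (1.0, 2.5) metres")
  }
  if (any(!is.finite(weight_kg) | weight_kg <= 30 | weight_kg >= 250)) {
    stop_config("weight must be in (30, 250) kg")
  }
  cm <- height_m * 100
  switch(method,
         dubois = 0.007184 * cm^0.725 * weight_kg^0.425,
         mosteller = sqrt(cm * weight_kg / 3600))
}

#' Cardiac output and cardiac index
#'
#' CO is the product of stroke volume and heart rate; the cardiac index
#' normalizes CO by body surface area and is the usual proxy for cardiac
#' strain during heat exposure.
#'
#' @param sv Stroke volume, mL. @param hr Heart rate, beats/min.
#' @return `compute_cardiac_output()`: CO in L/min.
#' @export
#' @examples compute_cardiac_output(70, 70)  # 4.9
compute_cardiac_output <- function(sv, hr) {
  assert_positive(sv, "sv"); assert_positive(hr, "hr")
  sv * hr / 1000
}

#' @rdname compute_cardiac_output
#' @param co Cardiac output, L/min. @param bsa Body surface area, m^2.
#' @return `compute_cardiac_index()`: cardiac index in L/min/m^2.
#' @export
compute_cardiac_index <- function(co, bsa) {
  assert_positive(co, "co"); assert_positive(bsa, "bsa")
  co / bsa
}

#' Construct a subject anthropometry profile
#'
#' @param subject_id Identifier. @param age Years. @param height Metres.
#' @param weight kg. @param bsa_method BSA formula, see [derive_bsa()].
#' @return One-row data.frame with derived `bsa` (m^2) and `bmi` (kg/m^2).
#' @export
#' @examples subject_profile("s1", 21.5, 1.80, 81.5)
subject_profile <- function(subject_id, age, height, weight,
                            bsa_method = "dubois") {
  n <- max(length(subject_id), length(age), length(height), length(weight))
  subject_id <- rep_len(as.character(subject_id), n)
  age <- rep_len(age, n); height <- rep_len(height, n); weight <- rep_len(weight, n)
  if (any(!is.finite(age) | age <= 0)) stop_config("age must be positive")
  bsa <- derive_bsa(height, weight, bsa_method)
  data.frame(subject_id = subject_id, age = age, height = height,
             weight = weight, bsa = bsa, bmi = weight / height^2,
             stringsAsFactors = FALSE)
}

#' Remington volume-factor table
#'
#' The Remington formula maps each pressure to an aortic "volume factor"
#' through a table that is not published in the source; predictions use
#' `SV = (VF(SAP) - VF(DAP)) * BSA` with linear interpolation between table
#' nodes. Supply the table here to make the formula applicable.
#'
#' @param pressure_mmhg Increasing pressures (mmHg).
#' @param volume_factor Matching non-decreasing volume factors (mL/m^2).
#' @return A `remington_vf_table` usable via the `vf_table` argument of the
#'   prediction functions.
#' @export
remington_vf_table <- function(pressure_mmhg, volume_factor) {
  stopifnot(length(pressure_mmhg) == length(volume_factor),
            length(pressure_mmhg) >= 2L)
  if (is.unsorted(pressure_mmhg, strictly = TRUE)) {
    stop_config("pressure nodes must be strictly increasing")
  }
  if (is.unsorted(volume_factor)) {
    stop_config("volume factors must be non-decreasing (monotone table)")
  }
  structure(list(pressure = as.numeric(pressure_mmhg),
                 vf = as.numeric(volume_factor)),
            class = "remington_vf_table")
}

# --- vectorized prediction core ---------------------------------------------

# data: data.frame with columns pp, sap, dap, age, weight, height, bsa, bmi, hr
# (any of which may be NA). Returns list(sv, applicable, skip_reason).
predict_formula_vec <- function(spec, data, vf_table = NULL,
                                lu_extra = c("constant", "omit")) {
  lu_extra <- match.arg(lu_extra)
  n <- nrow(data)
  cf <- spec$coef
  sv <- rep(NA_real_, n)
  applicable <- rep(TRUE, n)
  reason <- rep("", n)

  need <- spec$required_inputs
  colmap <- c(pp = "pp", sap = "sap", dap = "dap", age = "age",
              weight = "weight", height = "height", bsa = "bsa", hr = "hr")
  for (inp in need) {
    col <- colmap[[inp]]
    vals <- if (col %in% names(data)) data[[col]] else rep(NA_real_, n)
    miss <- !is.finite(vals)
    if (any(miss)) {
      applicable[miss] <- FALSE
      reason[miss] <- paste0("missing input: ", inp)
    }
  }

  if (!is.null(spec$applicability$bmi_max)) {
    over <- is.finite(data$bmi) & data$bmi > spec$applicability$bmi_max
    applicable[over] <- FALSE
    reason[over] <- sprintf("BMI %.2f exceeds applicability limit %.2f kg/m^2",
                            data$bmi[over], spec$applicability$bmi_max)
  }
  if (isTRUE(spec$applicability$requires_vf_table) && is.null(vf_table)) {
    applicable[] <- FALSE
    reason[] <- "no Remington volume-factor table supplied"
  }

  ok <- applicable
  if (any(ok)) {
    sv[ok] <- switch(spec$form,
      starr_linear = cf$a + cf$b * data$pp[ok] - cf$c * data$dap[ok] -
        cf$d * data$age[ok],
      jackson = cf$a + cf$b * data$sap[ok] - cf$c * data$dap[ok] -
        cf$d * data$age[ok],
      starr_bracket = cf$a + cf$b * data$pp[ok] -
        cf$c * (data$dap[ok] + cf$k * data$pp[ok]) - cf$d * data$age[ok],
      scaled_starr = cf$s * (cf$a + cf$b * data$pp[ok] - cf$c * data$dap[ok] -
        cf$d * data$age[ok]) + cf$t,
      power_anthro = cf$m * switch(spec$input_var,
        weight = data$weight[ok], bsa = data$bsa[ok],
        height = data$height[ok])^cf$p,
      linear_anthro = cf$m * switch(spec$input_var,
        weight = data$weight[ok], height_cm = data$height[ok] * 100) + cf$t,
      lu = {
        extra <- if (lu_extra == "constant") cf$c_extra else 0
        co <- cf$c0 + extra - cf$c_age * data$age[ok] +
          cf$c_weight * data$weight[ok]
        1000 * co / data$hr[ok]
      },
      remington = {
        vf <- function(p) stats::approx(vf_table$pressure, vf_table$vf,
                                        xout = p, rule = 2)$y
        (vf(data$sap[ok]) - vf(data$dap[ok])) * data$bsa[ok]
      },
      stop_config("unknown functional form '%s'", spec$form))
  }
  list(sv = sv, applicable = applicable, skip_reason = reason)
}

obs_to_predict_frame <- function(subject, obs) {
  pp <- if (!is.null(obs$pp)) obs$pp else derive_pulse_pressure(obs$sap, obs$dap)
  data.frame(
    pp = pp, sap = obs$sap %||% NA_real_, dap = obs$dap %||% NA_real_,
    hr = obs$hr %||% NA_real_,
    age = subject$age %||% NA_real_, weight = subject$weight %||% NA_real_,
    height = subject$height %||% NA_real_, bsa = subject$bsa %||% NA_real_,
    bmi = subject$bmi %||% NA_real_)
}

#' Predict stroke volume for one observation with one formula
#'
#' @param formula_id Registry key, see [formula_ids()].
#' @param subject One-row data.frame from [subject_profile()] (or a list with
#'   the same fields).
#' @param obs A list/one-row data.frame with `sap`, `dap`, and optionally
#'   `hr` (mmHg, mmHg, bpm); `pp` is derived.
#' @param registry Registry to use. @param vf_table Optional
#'   [remington_vf_table()]. @param lu_extra How to treat the orphaned
#'   `0.446` term of the Lu equation: `"constant"` (default) or `"omit"`.
#' @return A one-row data.frame (a prediction record): `formula_id`,
#'   `sv_predicted` (mL; `NA` when not applicable), `applicable`,
#'   `skip_reason`.
#' @details A missing required input (e.g. no HR for the Lu formula) is an
#'   error here; use [predict_all()] to convert such cases into per-record
#'   skip entries instead.
#' @export
#' @examples
#' s <- subject_profile("s1", age = 21.5, height = 1.80, weight = 81.5)
#' predict_sv("starr54_eq72", s, list(sap = 120, dap = 80))  # 59.1 mL
predict_sv <- function(formula_id, subject, obs, registry = sv_registry(),
                       vf_table = NULL, lu_extra = "constant") {
  spec <- formula_info(formula_id, registry)
  df <- obs_to_predict_frame(subject, obs)
  res <- predict_formula_vec(spec, df, vf_table = vf_table, lu_extra = lu_extra)
  if (!res$applicable[1] && startsWith(res$skip_reason[1], "missing input")) {
    stop_config("formula '%s': %s", formula_id, res$skip_reason[1])
  }
  data.frame(formula_id = formula_id, sv_predicted = res$sv[1],
             applicable = res$applicable[1], skip_reason = res$skip_reason[1],
             stringsAsFactors = FALSE)
}

#' Predict stroke volume with every registry formula
#'
#' Evaluates all 22 formulae on one observation, in registry order. Formula
#' failures (missing inputs, applicability constraints) become per-record
#' skip entries; the batch never aborts.
#'
#' @inheritParams predict_sv
#' @return 22-row data.frame of prediction records.
#' @export
predict_all <- function(subject, obs, registry = sv_registry(),
                        vf_table = NULL, lu_extra = "constant") {
  df <- obs_to_predict_frame(subject, obs)
  out <- lapply(registry, function(spec) {
    res <- predict_formula_vec(spec, df, vf_table = vf_table, lu_extra = lu_extra)
    data.frame(formula_id = spec$formula_id, sv_predicted = res$sv[1],
               applicable = res$applicable[1], skip_reason = res$skip_reason[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Vectorized predictions for a record table
#'
#' Joins anthropometry onto the observation table and evaluates every
#' requested formula on every record. This is the batch engine behind
#' [evaluate_formulae()] and [stratified_report()].
#'
#' @param observations Observation data.frame (see [read_observations()] for
#'   the schema): `subject_id`, `day`, `posture`, `condition`, `sap`, `dap`,
#'   `hr`, `sv_measured`.
#' @param subjects Subject profiles from [subject_profile()] /
#'   [generate_participants()].
#' @param formula_ids Formulae to evaluate (default: whole registry).
#' @inheritParams predict_sv
#' @return Long data.frame: one row per observation x formula, with `.row`
#'   (index into `observations`), `formula_id`, `sv_predicted`, `applicable`,
#'   `skip_reason`.
#' @export
predict_records <- function(observations, subjects,
                            formula_ids = NULL, registry = sv_registry(),
                            vf_table = NULL, lu_extra = "constant") {
  ids <- formula_ids %||% names(registry)
  m <- match(observations$subject_id, subjects$subject_id)
  if (anyNA(m)) {
    stop_config("observations reference unknown subject_id(s): %s",
                paste(unique(observations$subject_id[is.na(m)]), collapse = ", "))
  }
  df <- data.frame(
    pp = observations$sap - observations$dap,
    sap = observations$sap, dap = observations$dap,
    hr = if (is.null(observations$hr)) NA_real_ else observations$hr,
    age = subjects$age[m], weight = subjects$weight[m],
    height = subjects$height[m], bsa = subjects$bsa[m], bmi = subjects$bmi[m])
  n <- nrow(observations)
  out <- lapply(ids, function(id) {
    spec <- formula_info(id, registry)
    res <- predict_formula_vec(spec, df, vf_table = vf_table, lu_extra = lu_extra)
    data.frame(.row = seq_len(n), formula_id = id, sv_predicted = res$sv,
               applicable = res$applicable, skip_reason = res$skip_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
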