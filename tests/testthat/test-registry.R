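test_that("registry holds exactly 22 uniquely keyed formulae in stable order", {
  reg <- sv_registry()
  expect_s3_class(reg, "sv_registry")
  expect_length(reg, 22L)
  ids <- formula_ids(reg)
  expect_false(anyDuplicated(ids) > 0)
  expect_identical(ids[1], "starr54_eq72")
  expect_identical(ids[13], "bridwell56")
  expect_identical(ids[22], "cathcart53")
  # every required input appears among the fields a formula can consume
  for (e in reg) {
    expect_true(all(e$required_inputs %in%
                      c("pp", "sap", "dap", "age", "weight", "height",
                        "bsa", "hr")),
                info = e$formula_id)
  }
  expect_error(formula_info("nope"), "unknown formula_id")
})

test_that("pulse pressure derivation subtracts and validates", {
  expect_equal(derive_pulse_pressure(120, 80), 40)
  expect_equal(derive_pulse_pressure(135.5, 72.25), 63.25)
  expect_error(derive_pulse_pressure(80, 80), "sap > dap")
  expect_error(derive_pulse_pressure(120, -5), "sap > dap")
  # offending record is named
  expect_error(derive_pulse_pressure(c(120, 90), c(80, 95)), "2")
})

test_that("BSA formulae match hand arithmetic and reject bad input", {
  expect_equal(round(derive_bsa(1.80, 81.5, "dubois"), 2), 2.01)
  expect_equal(round(derive_bsa(1.80, 81.5, "mosteller"), 2), 2.02)
  expect_equal(derive_bsa(1.80, 81.5, "mosteller"), sqrt(180 * 81.5 / 3600))
  expect_error(derive_bsa(1.80, 81.5, "boyd"), "unknown BSA method")
  expect_error(derive_bsa(0.9, 81.5), "height")
  expect_error(derive_bsa(1.80, 20), "weight")
})

test_that("cardiac output and index follow their defining products", {
  expect_equal(compute_cardiac_output(70, 70), 4.9)
  expect_equal(compute_cardiac_index(4.9, 2.0), 2.45)
  expect_error(compute_cardiac_output(0, 70), "positive")
  expect_error(compute_cardiac_index(4.9, -1), "positive")
})

test_that("single-formula predictions reproduce worked examples", {
  s <- subject_profile("s", age = 21.5, height = 1.80, weight = 81.5)
  obs <- list(sap = 120, dap = 80)
  expect_equal(predict_sv("starr54_eq72", s, obs)$sv_predicted,
               100 + 0.5 * 40 - 0.6 * 80 - 0.6 * 21.5)  # 59.1
  expect_equal(predict_sv("starr54_eq68", s, obs)$sv_predicted, 63.885)
  expect_equal(round(predict_sv("desimone97_weight", s, obs)$sv_predicted, 1),
               81.7)
  s70 <- subject_profile("s", age = 30, height = 1.80, weight = 70)
  expect_equal(predict_sv("skrabal05_weight", s70, obs)$sv_predicted,
               0.77 * 70 + 29)  # 82.9
  # intercept-only evaluation of the linear form
  degenerate <- list(age = 0, weight = NA, height = NA, bsa = NA, bmi = NA)
  expect_equal(predict_sv("starr54_eq72", degenerate,
                          list(pp = 0, dap = 0))$sv_predicted, 100)
})

test_that("applicability constraints flag rather than compute", {
  heavy <- subject_profile("h", age = 25, height = 1.70, weight = 26 * 1.7^2)
  expect_gt(heavy$bmi, 25.25)
  rec <- predict_sv("desimone97_weight", heavy, list(sap = 120, dap = 80))
  expect_false(rec$applicable)
  expect_match(rec$skip_reason, "25.25")
  expect_true(is.na(rec$sv_predicted))
  # sv_predicted present iff applicable
  lean <- subject_profile("l", age = 25, height = 1.80, weight = 70)
  rec2 <- predict_sv("desimone97_weight", lean, list(sap = 120, dap = 80))
  expect_true(rec2$applicable && is.finite(rec2$sv_predicted))
})

test_that("predict_all emits one record per registry entry, never aborting", {
  s <- subject_profile("s", age = 21.5, height = 1.80, weight = 81.5)
  out <- predict_all(s, list(sap = 120, dap = 80, hr = 70))
  expect_identical(nrow(out), 22L)
  expect_identical(out$formula_id, unname(formula_ids()))
  # only Remington (no table) is inapplicable here
  expect_identical(out$formula_id[!out$applicable], "remington48")

  heavy <- subject_profile("h", age = 25, height = 1.70, weight = 80)
  out_h <- predict_all(heavy, list(sap = 120, dap = 80, hr = 70))
  desimone <- grep("^desimone", out_h$formula_id, value = TRUE)
  expect_length(desimone, 3L)
  expect_true(all(!out_h$applicable[out_h$formula_id %in% desimone]))
  expect_true(all(grepl("BMI", out_h$skip_reason[out_h$formula_id %in% desimone])))

  # missing HR: Lu flagged as skip in the batch, hard error in predict_sv
  vf <- remington_vf_table(c(40, 200), c(10, 60))
  out_nohr <- predict_all(s, list(sap = 120, dap = 80), vf_table = vf)
  expect_identical(out_nohr$formula_id[!out_nohr$applicable], "lu15")
  expect_match(out_nohr$skip_reason[out_nohr$formula_id == "lu15"],
               "missing input: hr")
  expect_identical(sum(is.finite(out_nohr$sv_predicted)), 21L)
  expect_error(predict_sv("lu15", s, list(sap = 120, dap = 80)),
               "missing input: hr")
})

test_that("Remington predictions interpolate a supplied volume-factor table", {
  vf <- remington_vf_table(c(60, 80, 120, 160), c(15, 20, 30, 38))
  s <- subject_profile("s", age = 21.5, height = 1.80, weight = 81.5)
  rec <- predict_sv("remington48", s, list(sap = 120, dap = 80), vf_table = vf)
  expect_true(rec$applicable)
  expect_equal(rec$sv_predicted, (30 - 20) * s$bsa)
  # interpolated midpoint
  rec2 <- predict_sv("remington48", s, list(sap = 100, dap = 70), vf_table = vf)
  expect_equal(rec2$sv_predicted, (25 - 17.5) * s$bsa)
  expect_error(remington_vf_table(c(80, 60), c(1, 2)), "increasing")
  expect_error(remington_vf_table(c(60, 80), c(2, 1)), "non-decreasing")
})

test_that("algebraically equivalent formulae agree to 1e-9 on random inputs", {
  inp <- random_inputs(2000, seed = 7)
  subs <- subject_profile(sprintf("r%d", seq_len(nrow(inp))),
                          inp$age, inp$height, inp$weight)
  obs <- data.frame(subject_id = subs$subject_id, sap = inp$sap, dap = inp$dap,
                    hr = inp$hr, sv_measured = 80,
                    posture = "supine", condition = "thermoneutral", day = 1)
  pred <- predict_records(obs, subs)
  wide <- function(id) pred$sv_predicted[pred$formula_id == id]
  expect_lt(max(abs(wide("jackson55") - wide("starr54_eq71"))), 1e-9)
  expect_lt(max(abs(wide("starr54_eq62") - wide("starr54_eq59b"))), 1e-9)
  expect_lt(max(abs((wide("starr54_eq64") - wide("starr54_eq59b")) - (-0.01))),
            1e-9)
})

test_that("canonical coefficients reproduce every pressure formula exactly", {
  inp <- random_inputs(500, seed = 9)
  s_ids <- sprintf("c%d", seq_len(nrow(inp)))
  subs <- subject_profile(s_ids, inp$age, inp$height, inp$weight)
  obs <- data.frame(subject_id = s_ids, sap = inp$sap, dap = inp$dap,
                    hr = inp$hr, sv_measured = 80,
                    posture = "supine", condition = "thermoneutral", day = 1)
  pred <- predict_records(obs, subs)
  for (id in names(sv_registry())) {
    cc <- canonical_coefficients(id)
    if (is.null(cc)) next
    got <- pred$sv_predicted[pred$formula_id == id]
    expect_lt(max(abs(got - canonical_predict(id, inp))), 1e-9)
  }
  expect_null(canonical_coefficients("desimone97_weight"))
  expect_null(canonical_coefficients("lu15"))
})

test_that("linear formulae are affine in jointly varied inputs and finite", {
  inp1 <- random_inputs(200, seed = 1)
  inp2 <- random_inputs(200, seed = 2)
  alpha <- 0.37
  for (id in c("starr54_eq72", "bridwell56", "grollman30", "jackson55")) {
    p1 <- canonical_predict(id, inp1)
    p2 <- canonical_predict(id, inp2)
    mix <- data.frame(pp = alpha * inp1$pp + (1 - alpha) * inp2$pp,
                      dap = alpha * inp1$dap + (1 - alpha) * inp2$dap,
                      age = alpha * inp1$age + (1 - alpha) * inp2$age)
    expect_lt(max(abs(canonical_predict(id, mix) -
                        (alpha * p1 + (1 - alpha) * p2))), 1e-9)
  }
  s <- subject_profile("s", age = 21.5, height = 1.80, weight = 70)
  out <- predict_all(s, list(sap = 120, dap = 80, hr = 70))
  expect_true(all(is.finite(out$sv_predicted[out$applicable])))
})
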