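---
title: "Validating stroke-volume prediction formulae: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating stroke-volume prediction formulae: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`svformula` implements a complete validation workflow for formulae that
predict left-ventricular stroke volume (SV, mL) from arterial pressure and
anthropometry, the kind of formulae a wearable or an automated cuff could
drive to estimate cardiac strain in workers exposed to heat. This vignette is
the package's account of the science: the models, the conventions chosen
where the literature is silent or garbled, and what the synthetic-data tests
do and do not establish.

## 1. The formula registry

The registry (`sv_registry()`) holds 22 formulae in a fixed presentation
order, each with the equation string as printed in its source, an interpreted
functional form, coefficients, units and applicability constraints. Most are
pressure-based,

$$\mathrm{SV} = a + b\,\mathrm{PP} - c\,\mathrm{DAP} - d\,\mathrm{age},$$

with PP the pulse pressure (SAP − DAP, mmHg). `canonical_coefficients()`
reduces every pressure-based row to this canonical form; it is also how the
synthetic generator inverts a formula.

Several printed rows required interpretation, recorded verbatim in the
registry JSON alongside the reading used:

* **Composite regressions** (Grollman, Warren, Liljestrand, Cathcart rows):
  the printed strings concatenate a scale factor with a Starr base-equation
  intercept (e.g. `1.0293+…` reads as `1.02 × (93 + …)`). They are
  implemented as `s·(a + b PP − c DAP − d age) + t`.
* **Bracketed PP terms** (Starr equations 62/63/64): `−0.57DBP + k·PP` is
  read as `−0.57·(DAP + k·PP)`, i.e. the coefficient distributes over the
  bracket. Under this reading equation 62 coincides *exactly* with equation
  59b and equation 64 differs from it by the constant −0.01 — consistent
  with their nearly identical published validation metrics — and the package
  asserts these identities as tests.
* **Height units**: metres for de Simone's `23.99·height^2.04` (≈ 80 mL at
  1.80 m), centimetres for Skrabal's `1.19·height − 112` (≈ 102 mL at
  180 cm). Each registry entry records its unit.
* **The Lu formula**: the printed string carries an orphaned `0.446` term
  whose multiplicand is unrecoverable. It is treated as cardiac output in
  L/min, `CO = 6.963 + 0.446 − 0.037·age + 0.013·weight`, converted to SV as
  `1000·CO/HR`; the extra term can be dropped via `lu_extra = "omit"`.
* **Remington**: implemented as `SV = (VF(SAP) − VF(DAP)) × BSA` with `VF` a
  user-supplied monotone volume-factor table (linear interpolation,
  `remington_vf_table()`). No table values are published in the source, so
  the formula is inapplicable by default and drops out of ranking runs with
  a warning. Whether the original divides or multiplies by BSA is ambiguous
  as printed; multiplication is used so that a factor difference of
  ~10 mL/m² at 2 m² yields an SV of plausible magnitude.
* **Applicability**: the three de Simone formulae were derived for
  normal-weight adults and are flagged inapplicable above BMI
  25.25 kg/m²; their metrics are computed on the reduced record set, with
  `n` reported per row.

Body surface area uses DuBois–DuBois by default
(`0.007184·cm^0.725·kg^0.425`), with Mosteller selectable; the validation
literature rarely names its BSA formula, and at the cohort means used here
(180 cm, 81.5 kg) both round to 2.0 m².

## 2. Cleaning protocol

Two filters run in a fixed order with exact accounting
(`clean_records()`):

1. **SV plausibility window**, inclusive at both ends (default 61–145 mL):
   beats outside it are attributed to movement artefact. Inclusivity was
   chosen because the protocol removes values *outside* the range.
2. **±2 SD blood-pressure screen**: a record is removed when its SAP *or*
   DAP deviates from its group mean by more than `k` sample SDs (n − 1
   denominator). Group statistics are computed once on the input — a single
   pass, no re-screening after removals. The grouping is
   subject × posture × condition by default: tilt and heat shift BP levels,
   and a coarser grouping would purge those physiological shifts as
   outliers. Groups with fewer than three records pass through unscreened.

Every input record lands in exactly one of retained / removed-by-SV /
removed-by-BP, and the filters are idempotent. The order is fixed because
permuting it changes the BP statistics; the package deliberately offers no
switch for that.

## 3. Metrics and rank aggregation

For each formula and stratum (posture ∈ {supine, hut60, both} ×
condition ∈ {thermoneutral, hot, both} — nine cells):

* Pearson *r* between measured and predicted SV;
* Hedges *g*: `|mean(x) − mean(y)| / s_pooled × J`, with
  `s_pooled = sqrt((sd_x² + sd_y²)/2)` and `J = 1 − 3/(4(2n−2) − 1)`;
  reported as a positive magnitude, switchable to uncorrected Cohen *d*.
  The pooled-SD construction mirrors the one used for the sizing effect
  size in §5;
* SSR = Σ(observed − predicted)², a *raw sum* — comparisons between
  formulae are only meaningful on the identical record set (see §6);
* bias = mean(observed − predicted), signed; ranking consumes |bias|.

`rank_formulae()` assigns competition ranks (|r| descending; |g|, SSR,
|bias| ascending; ties share the minimum rank — chosen because algebraically
identical formulae must share every rank) and sums them into a total score;
the lowest total wins. Undefined metrics (constant series, zero pooled SD)
rank last and are flagged rather than silently dropped.

Bland–Altman limits of agreement use the conventional 1.96 multiplier on the
sample SD of the differences, so `loa_high − loa_low = 2·1.96·sd_diff`
exactly; the bias equals `mean_bias()` by construction.
`loa_cv_ratio()` projects the limits onto a reference SV (e.g. 70 mL) and
expresses them as percentages of it; this is one possible reading of an
agreement "coefficient of variation" and is clearly labelled an
interpretation — it takes no part in validation decisions.

## 4. Synthetic data: what it emulates

`simulate_study()` emulates the shape of a confined-heatwave tilt study:

* 7 male subjects, anthropometry drawn from N(21.5, 1.2²) years (resampled
  into 19–23), N(1.80, 0.056²) m, N(81.5, 14.5²) kg. Note the age clamp is
  asymmetric about its mean, so the truncated mean is ≈ 21.31 y; tests
  check against the truncated-normal expectation. About half the simulated
  subjects exceed BMI 25.25, exercising the de Simone applicability path.
* 9 protocol days: 1–3 and 7–9 thermoneutral (25.4 °C work shift), 4–6 hot
  (35.4 °C); one daily supine then 60° head-up-tilt phase;
  `beats_per_phase = 100` by default — a thinned, exchangeable sample of
  the several hundred beats a 10-minute phase contains (tests and the
  acceptance script use 3–40 beats per phase; sizes are always stated at
  the call site).
* Latent SV per posture × condition cell: means/SDs default to the
  stratified measured summaries of the emulated study (supine 83.45 ± 12.56
  / 86.24 ± 16.87 mL, tilt 69.77 ± 6.28 / 69.51 ± 6.76 mL for
  thermoneutral/hot), decomposed into a subject-level intercept (SD 8 mL,
  capped at 80 % of the cell SD so the cell SD is preserved) plus beat
  noise. Tilt lowers SV and heat raises HR, as physiology dictates.
* DAP ~ N(70, 8²) supine and N(75, 8²) tilted, HR baseline N(65, 8²) with a
  +10 bpm orthostatic offset — conventional placeholder levels, since the
  emulated cohort's BP/HR summaries are not published. The pipeline's
  behaviour depends only on the coupling structure, not on these values.
* HR on hot days adds thermal cardiac reactivity × core-temperature offset
  (33 bpm/°C × 0.3 °C by default; a work shift at 35 °C raises core
  temperature only modestly in young adults).
* PP is obtained by *exactly inverting* the generating formula (default
  Starr eq. 72) from the latent SV, so `noise_sd = 0` makes the generating
  formula reproduce measured SV with r = 1 and SSR = 0.

**Noise placement.** The single coupling-noise parameter can enter two ways.
The default, `noise_target = "sv_measured"`, adds N(0, σ) to the *measured*
SV (reference-method error). This channel is formula-neutral: every
candidate formula faces the same irreducible error floor,
`E[resid_f²] = σ² + E[(latent − pred_f)²]`, which the generating law
minimizes — the property a parameter-recovery test needs. The alternative,
`noise_target = "pp"`, perturbs the pulse pressure instead (cuff/sensor
error); it is *unsuitable for recovery checks* because large PP noise
rewards formulae with shrunken PP coefficients — the classic
errors-in-variables attenuation — and a shrinking competitor (e.g.
Bridwell's b = 0.34 against the generating 0.5) then beats the generating
law in expected SSR. Both channels are exposed; only the default is used for
the recovery properties.

**Calibration.** `calibrate_noise_for_target_r()` bisects σ until the
generating formula's measured ~ predicted correlation on a large simulated
sample hits a target (common random numbers across iterations keep the
realized r monotone in σ). The shipped default σ = 14.95 mL was calibrated
once against target r = 0.65 and then frozen. Across independent 5 000-beat
runs the realized r is centred on 0.65 with a between-run SD of ≈ 0.03 —
dominated by the 7-subject cohort draw, not beat sampling — so a 0.60–0.70
band captures roughly 95 % of runs.

Consequences worth knowing:

* With σ on the measured channel, per-stratum *measured* SDs exceed the
  configured (latent) cell SDs by `sqrt(1 + σ²/sd²)`. The cell mean targets
  hold on the measured scale; the cell SD targets hold exactly at
  `noise_sd = 0`, which is how the SD-reproduction test checks them. A
  single additive-noise channel cannot deliver a combined r of 0.65 *and*
  the narrow tilt-stratum SDs simultaneously; real residuals achieve that
  combination through structured misspecification that no neutral noise
  model can imitate.
* The plausibility window interacts with the calibrated noise: tilt strata
  (latent mean ≈ 69.6 mL) lose 20–30 % of beats below 61 mL, and because
  removal correlates with the noise sign, retained residuals shift by a few
  mL. Recovery checks therefore run on the generator's own output — which
  contains no artefacts to clean — while the filters are validated
  separately against `inject_artifacts()`' exact corruption ledger.

`inject_artifacts()` corrupts a seeded subset of records (SV strictly
outside the window, and/or SAP shifted far beyond the ±2 SD screen) and
returns the ledger, so filter removal counts can be compared with ground
truth record-for-record.

All generation is Mersenne–Twister with inversion sampling for normals,
locally scoped: identical seeds give identical output on every platform and
callers' RNG streams are untouched. Truncation is by resampling, never
clipping, preserving distribution shape near the bounds.

## 5. Power analysis

`pooled_effect_size(m1, s1, m2, s2)` returns
`dz = |m1 − m2| / sqrt((s1² + s2²)/2)`; for the published comparison of
thermodilution (123 ± 28 mL) against finger photoplethysmography
(87 ± 14 mL) this gives dz = 1.63. `paired_t_power()` is exact noncentral-t
arithmetic — df = n − 1, noncentrality dz·√n, the lower-tail rejection
region included — and `min_sample_size()` walks n upward to the smallest
power ≥ target.

At dz = 1.63, α = 0.05 and power 0.95 the exact two-tailed minimum is **8**
pairs (power at 7 is 0.9454) and the one-tailed minimum is 6. The widely
used figure of 7 participants for this design is not reproducible from
these settings by exact noncentral-t computation under either tail choice;
the package reports the exact values and leaves the discrepancy visible
rather than adjusting the routine toward a desired output. Tails default to
two, flagged here because sizing reports often leave the choice unstated.

## 6. Ranking on unequal n

Raw SSR grows with the number of pairs, so a formula whose applicability
constraint removes subjects competes on a smaller sum. The ranking tables
keep the field convention — every applicable formula is ranked on its own
record set, with `n` printed per row — but the parameter-recovery
properties compare SSR only among formulae evaluated on the identical
record set (`n == max(n)`), since with roughly half the synthetic subjects
above the BMI cap a reduced-n formula would otherwise win mechanically.
Readers of the ranking CSVs should apply the same caution the `n` column
invites.

## 7. Known limitations

* The generator reproduces the *distributional shape* of study data, not
  its physiology: no waveform synthesis, no baroreflex or thermoregulatory
  dynamics beyond a configured HR offset, independent beats within a phase
  (real beats are autocorrelated), and placeholder BP/HR levels. Passing
  recovery tests shows the pipeline's statistics and ranking machinery are
  sound — not that any formula is accurate on real upright, heat-stressed
  humans.
* A neutral additive noise channel cannot reproduce published per-stratum
  metric values (r per cell, SSR magnitudes); those depend on the original
  7-subject dataset, which is not deposited. The package therefore
  validates structure (exact algebraic identities, oracle-matched metrics,
  ledger-exact filters, generating-law recovery) rather than table values.
* The Lu row's orphaned term and the Remington volume-factor table are
  unrecoverable from the printed sources; both interpretations are explicit,
  configurable and excluded from default conclusions.
* `loa_cv_ratio()` is an interpretation of an ambiguous agreement ratio and
  should not be treated as a standard quantity.

## 8. Reproducing the headline numbers

```{r, eval = FALSE}
# from the repository root, against the installed package
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script recomputes, from scratch: dz and the exact minima/power of §5,
BSA at the cohort means, the (1, 11, 1, 2) → 15 rank-aggregation total, the
generating-formula SSR recovery rate over 50 seeded runs
(`beats_per_phase = 30`), the realized-correlation distribution at ~5 000
beats over 20 runs, the cleaning-versus-ledger agreement, and the maximal
deviations of the algebraic-equivalence and metric-oracle checks on 10⁴
random inputs. Every number in this vignette and the README is produced by
those computations or by the test suite; none is asserted from memory.
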