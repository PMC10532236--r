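---
title: "Measuring GFR from plasma iohexol clearance: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring GFR from plasma iohexol clearance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iohexolGFR)
```

## The measurement model

Iohexol is an exogenous filtration marker: it is injected as an
intravenous bolus, distributes between plasma and extracellular space,
and is removed essentially only by glomerular filtration. Its plasma
concentration after a bolus dose $D$ therefore follows a two-compartment
disposition,

$$C(t) = A e^{-\alpha t} + B e^{-\beta t},$$

with a fast distribution exponent $\alpha$ and a slow elimination
exponent $\beta$. The macro constants relate to the micro parameters
(central volume $V_1$, peripheral volume $V_2$, intercompartmental
clearance $Q$, elimination clearance $CL$) through the standard algebra
implemented in `pk_parameters()`: $k_{10} = CL/V_1$, $k_{12} = Q/V_1$,
$k_{21} = Q/V_2$; $\alpha + \beta = k_{10} + k_{12} + k_{21}$ and
$\alpha\beta = k_{10}k_{21}$. Two identities anchor all downstream
arithmetic and are enforced by tests:

* $C(0) = A + B = D/V_1$ (bolus initial condition), and
* $D / (A/\alpha + B/\beta) = CL$ — the dose over the full
  area under the curve equals the clearance.

### Slope-intercept clearance and its correction

The clinical protocol draws only three samples, at nominally 120, 180
and 240 minutes, when the distribution phase has decayed. On that
window $\ln C$ is linear in $t$: `fit_slow_compartment()` fits it by
ordinary least squares, giving the extrapolated zero-time intercept
$C_0' = e^{\text{intercept}}$ and $\beta = -\text{slope}$. The
monoexponential extrapolated over all time has
$AUC = C_0'/\beta$, and the slope-intercept clearance is
$C2 = D / AUC$.

This $AUC$ is smaller than the true two-compartment $AUC$ (it misses the
distribution-phase area), so $C2$ systematically **over**-estimates the
GFR. The Bröchner–Mortensen quadratic corrects the overestimate:

$$\mathrm{GFR} = 0.990778\,C2 - 0.001218\,C2^2 \quad(\text{mL/min}).$$

`bm_correct()` evaluates exactly this polynomial. It is strictly
increasing and below the identity on the physiologic range; its
derivative vanishes near 407 mL/min, far outside any clinical value, and
inputs above 400 mL/min are flagged rather than trusted. The corrected
GFR is normalized to the 1.73 m² reference body surface area
(`normalize_bsa()`, GFR × 1.73/BSA) **after** the correction: the
correction is a model of absolute clearance, so it is applied to the raw
C2 in mL/min and scaling to the reference body size happens last. (The
alternative order — normalize, then correct — appears in parts of the
literature; with typical adult BSAs the difference is about 1–2 % of the
result. The package exposes the two steps separately so either
composition is available, but `compute_mgfr()` uses correct-then-
normalize.)

### Why three points, and the fail-closed contract

On exact monoexponential data two points already determine the line; the
third point adds no information but makes *errors visible*: wrong draw
times, mislabeled tubes or dosing mistakes show up as a depressed
$R^2$. `compute_mgfr()` therefore withholds (never defaults) a result
when $R^2$ falls below a threshold, when any concentration is below the
quantification limit (with only three points there is no defensible
exclusion or imputation), when a draw is missing, or when the curve does
not decay. Withheld results keep their diagnostics and a
machine-readable reason, and appear in the LIS file with
`status = "withheld"` — auditability matters in a clinical-adjacent
pipeline, so rows are never silently dropped.

Numerical choices in this chain:

* **Log base.** The protocol only requires "the log transformation"; any
  fixed base gives the identical clearance, since slope and intercept
  rescale together. The natural log is used, and a test asserts the
  two-point/three-point equivalence on exact data.
* **$R^2$ threshold, default 0.98.** No numeric threshold is standard;
  0.98 flags gross timing/dosing errors while passing routine analytical
  noise (at 4 % proportional concentration noise about 95 % of simulated
  three-point batches clear it; with area noise stacked on top the pass
  rate drops and the gate bites harder — the GFR estimate itself is
  computed either way and only its *reporting* is gated). Configurable
  via `gfr_config()`.
* **Elapsed time** is always computed from the recorded injection and
  draw timestamps, not the nominal schedule; a test asserts invariance
  under a common shift of all timestamps. Draws before 120 min are
  flagged as potentially distribution-contaminated.
* **Units.** Concentrations in µg/mL (≡ mg/L), dose in mg, time in min,
  clearance reported in mL/min. The single L→mL conversion lives in
  `slope_intercept_clearance()`.

## Quantitation

Specimens are quantified from the analyte/internal-standard peak-area
ratio, which cancels injection-volume and ionization drift (a test
asserts the fit is invariant to a uniform rescaling of all areas).
`fit_calibration()` regresses ratio on nominal concentration:

* **Weighting, default 1/x.** The 5–1000 µg/mL range spans a factor of
  200; unweighted least squares lets the top calibrator dominate and
  degrades low-end accuracy. Inverse-concentration weighting is the
  usual bioanalytical choice and is the default, with `"none"`
  available.
* **Blanks excluded, intercept free.** The curve is fit to the six
  non-zero standards; it is not forced through zero.
* **Acceptance.** Each calibrator must back-fit within ±15 % of nominal
  (duplicates at a level are averaged for the recovery report, though
  every point enters the regression); one failing level flags the curve
  rejected (a hard failure if configured so). QC levels are judged by
  ±15 % recovery within a batch and by the CV ≤ 15 % rule across
  replicates — CV is undefined for a single injection, which is why the
  within-batch rule is recovery-based.

`back_calculate()` inverts the line and never truncates: results below
the LOQ or above the top calibrator are flagged (`below_loq`,
`above_range`) and the clearance layer decides what to do.

## Method-validation statistics

The `validation_stats` functions implement the laboratory's validation
battery as closed forms:

* **LOD** = blank mean + 3 SD; **LOQ** = max(concentration at which the
  between-day CV profile crosses 20 %, blank mean + 10 SD). The CV
  crossing is located by log-linear interpolation between bracketing
  tested levels, since precision profiles are close to linear on a log
  concentration axis. With the blank statistics 0.30 ± 0.28 µg/mL this
  definition yields 3.10 µg/mL; a signal-to-noise-based LOQ (the other
  common convention) is not computable from summary statistics, so the
  package documents the definitional difference and uses 3.3 µg/mL as
  the default reporting threshold for specimen flagging.
* **Precision** is summarized per level and design (within-run
  5 extractions × 4 injections; between-day 2 × 2 × 5 days; both n = 20)
  as the pooled mean and total CV, matching how validation tables are
  presented. A nested variance-component decomposition was considered
  and deliberately left out: the acceptance rule operates on total CV.
* **Carryover** follows the injection-sequence formula
  $[L_1 - (L_3+L_4)/2] / [(H_2+H_3)/2 - (L_3+L_4)/2] \times 100$ with a
  strict < 1 % rule; $L_2$ and $H_1$ are part of the sequence but not
  the formula.
* **Deming regression** (errors in both methods) is used for
  method comparison. The error-variance ratio defaults to 1 — two
  LC-MS/MS methods of comparable precision — and is configurable; as the
  ratio tends to ∞ the estimator converges to OLS of y on x and as it
  tends to 0 to the inverse OLS, which the tests verify numerically.
  The slope CI uses the leave-one-out jackknife, the common
  clinical-chemistry practice (bootstrap adds little at n ≈ 40 and costs
  determinism). **Bland–Altman** agreement uses absolute differences by
  default with a percent-difference option for concentration-
  proportional disagreement.

## The simulator: what it emulates, and what it does not

`simulate_profile()`/`simulate_study()` generate the study conditions
end to end: biexponential decay sampled at 120/180/240 min, proportional
Gaussian noise on concentration and on the instrument area ratio, a full
batch layout (blanks, six calibrators, three QCs, patient draws), order
tables with timestamps and BSA, and a ground-truth sidecar.

Default parameters, chosen once as a realistic healthy-adult setting and
not revisited: $V_1 = 6.5$ L, $V_2 = 5.5$ L, $Q = 0.1$ L/min, dose
$= 5\ \mathrm{mL} \times 647.1\ \mathrm{mg/mL} = 3235.5$ mg, noise CV
4 % (matching observed analytical CVs of 2.7–4.4 %). These place the
120–240 min concentrations of subjects with clearance 60–120 mL/min
inside the assay's 10–500 µg/mL working window, and give the
slope-intercept + correction chain a zero-noise recovery error of 6–9 %
— the residual bias of approximating a two-compartment decay by its
terminal phase, which is what the published correction is built to keep
within about 10 %.

The noise model is proportional Gaussian with redraw on non-positive
values (redraws are counted and warned about). The simulator does *not*
emulate: absorption or infusion kinetics (bolus only), three-compartment
behavior, inter-occasion or circadian variability, hemolysis/lipemia
interference, chromatographic integration errors, or barcode/clerical
errors. Passing recovery tests therefore demonstrates correctness of the
calculation chain under the stated disposition model and noise — not
robustness of the wet method to matrix pathology.

## Problem sizes and determinism

The test suite uses 100–200 seeded replicates for Monte-Carlo checks
(calibration linearity, CI coverage, CV recovery) and 150–500 replicates
per clearance grid point for parameter recovery; these sizes give
Monte-Carlo standard errors comfortably below the margins being asserted
while keeping the whole suite under a minute. All randomness flows
through explicit seeds (`with_local_seed()` restores the caller's RNG
state), and the pipeline — simulate → parse → quantitate → compute →
write — is byte-reproducible under a fixed seed, which a test asserts at
the file level.

## Known limitations

* The three-point 2–4 h protocol is only valid for moderate-to-normal
  kidney function; at GFR < 60 mL/min the slow phase is under-sampled
  and extended protocols (8–24 h draws) are required. The package flags
  low results via the KDIGO classification but does not implement
  extended-protocol models, nor single- or two-sample estimators.
* The quadratic correction is applied to absolute clearance before BSA
  normalization (see above); laboratories following the other convention
  will see ~1–2 % systematic differences.
* Patient data never support a full two-compartment fit (three points
  cannot identify four parameters); only the simulator knows both
  phases, which is exactly what makes it usable as a recovery oracle.
* The instrument and order CSV dialects are engineering definitions (no
  vendor schema is standardized); a column map supports renamed headers.
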