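---
title: "Methods: meta-analytic carboplatin dosing and the modified Calvert formula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analytic carboplatin dosing and the modified Calvert formula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbodose)
```

## The problem

Carboplatin is dosed to a target exposure (AUC, mg·min/mL) rather than to
body size, through the Calvert relation

$$\mathrm{Dose\ (mg)} = \mathrm{target\ AUC} \times (\mathrm{GFR} + 25),$$

where GFR + 25 approximates total carboplatin clearance (renal filtration
plus a 25 mL/min non-renal term). In routine practice GFR is replaced by an
estimate — classically Cockcroft–Gault creatinine clearance (CrCL), more
recently CKD-EPI eGFR de-normalized from mL/min/1.73 m² to absolute mL/min
by the patient's body surface area. In populations with preserved renal
function (CrCL ≥ 55 mL/min), small systematic differences between these
estimators translate into clinically meaningful dose differences.

`carbodose` implements a simulation framework for judging such formula
choices: it pools published population-PK typical values into a single
two-compartment carboplatin model, predicts each patient's 24-h exposure
under a candidate dose formula, and scores formulas by the fraction of
patients attaining the 4–6 mg·min/mL target band. A modified formula

$$\mathrm{Dose} = \mathrm{target\ AUC} \times (\mathrm{eGFR_{abs}} + 25 + \alpha)$$

adds an integer constant $\alpha$ (mL/min, swept over −25…+25) to the
non-renal term, and the sweep identifies the $\alpha$ that reduces
under-exposure without degrading attainment or increasing over-exposure.

## Pooling published PK estimates

`carbo_pool()` performs an inverse-variance random-effects meta-analysis of
published fixed-effect estimates of CL (L/h), V1 (L), K12 and K21 (1/h),
study by study, parameter by parameter. Reported uncertainties are
harmonized with `to_standard_error()`: an RSE (%CV) becomes
$SE = \hat\theta \cdot RSE/100$ on the linear scale and $RSE/100$ on the log
scale (delta method).

Three configuration levers exist because the published analyses of this
kind rarely state them:

* **Pooling scale** (`scale`, default `"log"`). PK parameters are strictly
  positive and their published confidence intervals tend to be
  multiplicatively symmetric, which points to log-scale pooling; linear
  pooling is retained as an option.
* **τ² estimator** (`tau2_method`, `"REML"` default, `"DL"` optional), both
  delegated to `metafor::rma()`.
* **Weighting** (`weighting`). `"inverse_variance"` is the standard RE
  estimator. `"equal"` is the τ²-dominant limit of the same model: when
  between-study variance dwarfs the within-study variances — the regime
  indicated by I² values near 100% — the RE weights $1/(v_i+\tau^2)$ become
  effectively equal and the pooled value is the unweighted mean on the
  pooling scale, with the CI taken from the spread of the study effects.
  With the packaged study table, the printed I² of the source analysis
  (95–100% on every parameter) is far above what the printed RSE/SE values
  imply (Cochran's Q for clearance is only ≈ 2.9 on either scale), so the
  source's within-study variances must have been constructed much smaller
  than the printed uncertainties — consistent with per-subject rather than
  per-study precision. The equal-weight limit reproduces that regime
  without needing the unpublished study sizes, and `scale = "linear",
  weighting = "equal"` is the configuration under which the packaged table
  reproduces the published pooled values most closely (CL, V1, K12 within
  1%). An experimental `se_mode = "se_over_sqrt_n"` divides reported SEs by
  $\sqrt{N}$ for sensitivity analysis when study sizes are available.

Parameters reported by a single study (V2, Q here) pass through with their
own Wald CI and are excluded from simulation; micro-constants are never
imputed from Q/V2. Pooled K21 is the one value that resists reproduction:
every configuration yields 0.19–0.21 h⁻¹ against a published 0.18 h⁻¹; the
package reports its computed value rather than forcing a match.

Units are standardized once at the end (`standardize_units()`):
CL × 1000/60 → mL/min, rate constants ÷ 60 → 1/min, so the Calvert formula
and the exposure integral operate natively in minutes, mg and mL.

## The exposure model

Exposure is computed from the two-compartment model with constant-rate
infusion into the central compartment, at typical values only — no
inter-individual variability, matching the simulation design the framework
reproduces. The central concentration is piecewise biexponential with
hybrid constants $\lambda_{1,2}$, the roots of
$\lambda^2-(k_{10}+k_{12}+k_{21})\lambda+k_{10}k_{21}=0$
($k_{10}=CL/V_1$). `auc()` integrates the closed form exactly; no ODE
solver runs inside the package (a deSolve integration of the mass balance
serves as the independent oracle in the test suite, agreeing to better than
1e-6 relative error over a ±50% parameter grid).

Numerical choices:

* The 24-h AUC window is anchored at infusion start (0–1440 min, 180-min
  infusion). Anchoring at infusion end would change the AUC by well under
  1% of the tail; the infusion-start anchor is the conventional reading.
* $\lambda_2$ is computed from the root product ($\lambda_2 =
  k_{10}k_{21}/\lambda_1$) to avoid subtractive cancellation.
* Repeated hybrid roots (possible only on a measure-zero parameter set,
  never at pooled values) are rejected at construction with a clear error;
  no confluent-exponential branch is implemented.
* $AUC_{0-\infty}=\mathrm{dose}/CL$ exactly, so the window fraction
  $f_{24}=AUC_{0-24\,h}/AUC_{0-\infty}$ is a deterministic constant per
  parameter set ($f_{24}=0.9859$ at CL 131.8 mL/min, V1 15.39 L,
  K12 0.002 min⁻¹, K21 0.003 min⁻¹), making every attainment result
  auditable as $\mathrm{dose}\cdot f_{24}/CL$.

An optional sensitivity extension (`exposure()` over user-supplied
parameter draws, e.g. CL resampled within its meta-analytic CI) is
available through the ordinary function surface; it is an extension, not
part of the reference analysis.

## Renal function and dosing

`cockcroft_gault()`, `ckd_epi()` (2009 and race-free 2021), `bsa()`
(Mosteller and Du Bois) and `bsa_readjust_egfr()` supply the dosing
covariates. Defaults where the convention is not fixed by the source
datasets: CKD-EPI **2021** (current reporting standard; 2009 selectable,
used without a race coefficient), BSA **Mosteller** (ubiquitous in oncology
EHRs; Du Bois selectable). Serum creatinine is mg/dL at the interface;
µmol/L cohort columns are converted (÷ 88.4) on read. No cap is applied to
the renal metric by default — the 125 mL/min cap common in some protocols
is available (`gfr_cap`) but off, because the emulated datasets extend
beyond 120 mL/min. Doses are kept at full floating precision; rounding to
1 mg happens only in report tables.

## Attainment and the α sweep

`classify()` uses four exhaustive bands: under (< 4), target (4–6
inclusive), gap (6–7 exclusive) and over (≥ 7 mg·min/mL). The gap band is
reported explicitly because the three conventional headline proportions
(target/under/over) need not sum to 100%.

`select_alpha()` encodes the selection rule: against the α = 0 baseline
(the conventional eGFR formula), an α qualifies if under-exposure and
over-exposure do not increase and target attainment does not decrease,
with at least one strict improvement. The "strict improvement in at least
one band, no degradation elsewhere" reading is deliberate: a rule requiring
strict improvement in *all* bands would reject an α whose attainment and
over-exposure are identical to baseline but whose under-exposure is lower,
which is exactly the pattern the modification aims for. Among qualifying α
the smallest |α| wins, ties broken toward the positive sign — the minimal
perturbation of the established formula. Selection always uses unrounded
percentages; one-decimal rounding is applied only in reports.

## The virtual cohort generator

The reference datasets (a Korean hospital EHR extract and a Portuguese
outpatient oncology dataset) are not public; `generate_cohort()` builds a
154-patient virtual cohort reproducing their published structure: four
strata (2 and 58 patients at target AUC 5 and 6 in dataset 1; 57 and 37 in
dataset 2) with published normalized-eGFR means, SDs and ranges, all
female, all with CrCL ≥ 55 mL/min.

Per stratum the generator samples eGFR from a truncated normal on the
published mean/SD/range and then applies a deterministic moment correction
so the stratum carries the published sample mean and SD *exactly* — the
published moments are the source cohorts' sample statistics, and each
(mean, SD, range) triple is attainable within its printed range (for the
n = 2 stratum the corrected sample is forced to the two printed range
endpoints, which are evidently the two data points). Serum creatinine is
back-solved through the CKD-EPI equation (`invert_ckd_epi()`, unique root
by monotonicity), so creatinine, eGFR, CG CrCL and BSA are mutually
consistent per patient. Patients failing the CrCL filter receive fresh
demographics, leaving the moment-matched eGFR sample intact.

Age/weight/height distributions are **not** published; the generator uses
documented guesses (truncated normals over plausible adult-oncology
ranges), flagged in the cohort's `generator` attribute. Two presets shape
the joint CrCL–eGFR distribution mechanistically — both metrics always
consume the same creatinine; no noise is injected:

* `mode = "consistent"`: demographics centred (age ≈ 48, weight ≈ 65 kg)
  so CG CrCL tracks absolute eGFR closely.
* `mode = "biased"` (default): an older, lighter population (age ≈ 63,
  weight ≈ 56 kg), in which CG systematically diverges from CKD-EPI-derived
  absolute eGFR and CrCL-based dosing consequently under-doses relative to
  eGFR-based dosing — the mechanism behind the published comparison.

What passing tests on this cohort do and do not show: the generator
reproduces the published renal-function *marginals* and the qualitative
formula ordering (eGFR-based dosing attains more, under-exposes less; sweep
curves monotone in α), and these are frozen as seeded regression values.
It cannot reproduce the published headline percentages (66.0/88.3% etc.),
which depend on the unpublished joint distribution of demographics,
creatinine and BSA in the real 154 patients; the package makes no claim to
them. The n = 2 stratum's printed SD (17.03) is a two-point statistic and
is not attainable at scaled-up n inside its printed range; scaled-up
calibration checks therefore assert SDs on the other strata only.

## Pipeline and reproducibility

`run_pipeline(carbo_config(...))` executes pool → cohort → dose → simulate
→ sweep → report and writes `config.json`, `pooled.json`, `cohort.csv`,
`doses.csv`, `exposures.csv`, `sweep.csv` and `report.md` into the output
directory; every numeric table is regenerable from `pooled.json` +
`cohort.csv` alone, and reruns under the same config and seed are
byte-identical. The function surface is the interface — the package is an
analysis library, not a shell tool — and the run header logs the
meta-analysis configuration, the main reproducibility lever. The packaged
reference cohort uses seed 1001.

Problem sizes used throughout the packaged analyses and tests: 3-study
pooling, a 154-patient cohort (×10 for calibration checks), the 51-point α
grid, and PK validation on a handful of parameter-grid points — the whole
suite runs in seconds.

## Known limitations

* Exposure is model-predicted at typical values; no measured
  concentrations, no inter-individual variability, no clinical outcomes.
* The pooled model inherits whatever mixed-tumor populations the source
  models were fitted on.
* The equal-weight pooling configuration is an inference about the source
  analysis's variance construction, documented rather than certain.
* Single-cycle dosing only; no covariate-dependent clearance, no free
  platinum kinetics, no Bayesian individual estimation.
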