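# carbodose

Carboplatin dosing analysis by meta-analytic population pharmacokinetics:
evaluate and optimize Calvert-type dose formulas in patients with preserved
renal function.

Carboplatin is dosed to a target exposure through the Calvert relation
**Dose (mg) = target AUC × (GFR + 25)**, with GFR in practice replaced by an
estimate — Cockcroft–Gault creatinine clearance (CrCL) or CKD-EPI eGFR
de-normalized to absolute mL/min by body surface area (eGFR_abs =
eGFR × BSA/1.73). `carbodose` provides the full simulation chain for judging
such choices:

1. **Pooling** (`carbo_pool()`): inverse-variance random-effects
   meta-analysis of published population-PK typical values (CL, V1, K12,
   K21) across studies, with log/linear pooling scales, DL/REML τ²
   estimators and an equal-weight (τ²-dominant) mode, returning a fitted
   `carbo_pk` model with `print`/`summary`/`coef`/`confint`/`predict`/`plot`
   methods.
2. **Exposure** (`auc()`, `concentration()`, `predict()`): closed-form
   two-compartment constant-rate-infusion model at the pooled typical
   values; AUC over 24 h after the start of a 3-h infusion, with
   AUC₀₋∞ = dose/CL exactly.
3. **Attainment** (`classify()`, `cohort_proportions()`, `alpha_sweep()`,
   `select_alpha()`): score formulas by the fraction of patients in the
   4–6 mg·min/mL target band (under < 4; over ≥ 7; the 6–7 gap band is
   reported explicitly), and sweep the modified formula
   **Dose = target AUC × (eGFR_abs + 25 + α)** over α = −25…+25 mL/min.
4. **Virtual cohorts** (`generate_cohort()`): seeded 154-patient cohorts
   reproducing the published stratum structure of two retrospective
   breast-cancer datasets (strata of 2/58/57/37 patients at target AUC 5/6,
   published eGFR means/SDs/ranges carried exactly, CrCL ≥ 55 mL/min),
   with creatinine back-solved through CKD-EPI so all renal metrics are
   mutually consistent per patient.
5. **Pipeline** (`run_pipeline()`): pool → cohort → dose → simulate →
   sweep → report, writing a reproducible bundle (`pooled.json`,
   `cohort.csv`, `doses.csv`, `exposures.csv`, `sweep.csv`, `report.md`).

See the methods vignette (`vignettes/carboplatin-dosing.Rmd`) for the model,
its assumptions and the design decisions.

## Worked example

```r
library(carbodose)

fit <- carbo_pool()          # pool the packaged published estimates
fit
#> Meta-analytic carboplatin PK model (two-compartment, typical values)
#> Pooling: random effects, log scale, tau2 = REML, inverse-variance weights
#> Studies: 12 rows, 3 distinct sources
#>
#> Typical values: CL 133.8 mL/min, V1 15.34 L, K12 0.002226 1/min, K21 0.003572 1/min

cohort <- generate_cohort(seed = 1001)   # packaged 154-patient reference cohort
pred <- predict(fit, cohort, formula = "egfr")
head(pred, 3)
#>                  id dataset_label target_auc dose_mg auc_pred auc_inf category
#> 1 dataset1_auc5_001      dataset1          5   583.5    4.316   4.360   target
#> 2 dataset1_auc5_002      dataset1          5   660.0    4.882   4.931   target
#> 3 dataset1_auc6_001      dataset1          6   719.4    5.321   5.375   target

alpha_sweep(cohort, fit)
#> Alpha sweep over [-25, 25] (n = 154 patients)
#> Baseline (alpha = 0): target 83.1%, under 13.6%, gap 3.2%, over 0.00%
#> Selected alpha = 1: target 84.4%, under 11.7%, gap 3.9%, over 0.00%
```

Reading the output: each patient's dose is target AUC × (eGFR_abs + 25);
`auc_pred` is the model-predicted exposure over 24 h (always slightly below
`auc_inf` = dose/CL because the window truncates the tail). On this cohort
the conventional eGFR formula places 83.1% of patients in the 4–6 band with
13.6% under-exposed; adding α = 1 mL/min to the non-renal term is selected
because it reduces under-exposure (11.7%) without increasing over-exposure —
the same decision pattern as CrCL-vs-eGFR comparisons in the literature,
where CrCL-based dosing fares far worse (here 50.0% target, 24.0% under):

```r
cohort_proportions(cohort, "crcl", fit)
#>     n n_under pct_under n_target pct_target n_gap pct_gap n_over pct_over
#> 1 154      37        24       77         50    21    13.6     19     12.3
```

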