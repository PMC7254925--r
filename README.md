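# dietvalid

Measurement error models for dietary validation studies with recovery
biomarkers.

## The problem

Short self-report dietary instruments — online 24-hour questionnaires and
interviewer-administered multiple-pass recalls — measure intake with
additive, multiplicative and *person-specific* error.  In a prospective
diet–disease study this attenuates log relative risks and erodes power, and
because person-specific biases are shared between self-report tools,
validating one self-report tool against another is not enough.  The remedy
is a biomarker-based validation study: repeated 24-hour urine collections
(nitrogen for protein, potassium; calibrated sucrose + fructose for total
sugars), energy expenditure from calorimetry + accelerometry, and a
measurement error model that compares all instruments simultaneously.

`dietvalid` is for biostatisticians and nutritional epidemiologists who run
or re-analyse such studies.  It provides, as a tested package:

* the three-instrument latent true-intake model
  (Q<sub>ij</sub> = μ<sub>Qj</sub> + β<sub>Q0</sub> + β<sub>Q1</sub>T<sub>i</sub> + r<sub>i</sub> + ε<sub>ij</sub>,
  similarly for the recall F with bias s<sub>i</sub>, and
  M<sub>ij</sub> = μ<sub>Mj</sub> + T<sub>i</sub> + v<sub>ij</sub> for the
  biomarker, correlated (r, s), all on the log scale), fitted by
  full-information maximum likelihood under missing-at-random;
* attenuation factors λ<sub>k</sub> = β₁σ²_T/(β₁²σ²_T + σ²_b + σ²_w/k) and
  correlations with true intake ρ<sub>k</sub> for the mean of k repeat
  administrations, with participant-bootstrap and delta-method intervals;
* the closed-form extrapolation that recovers λ<sub>k</sub>, ρ<sub>k</sub>
  for any k from a published (λ₁, λ₂, ρ₁) triple;
* biomarker construction from raw records: nitrogen → protein (81%
  excretion, Kjeldahl 6.25), potassium (80%), the age/sex sugar calibration
  M\* = M − 1.67 − 0.02·S + 0.71·A, PABA completeness rules with optional
  rescaling to 93% recovery, TEE = (REE + AEE)/0.9 with the >5%
  weight-change exclusion, nutrient densities, geometric means and
  log-scale Bland–Altman percentage differences;
* a synthetic cohort generator with exactly the model's statistical
  structure (160 adults, 3 cycles, realistic missingness and urine
  completeness), so the entire pipeline is testable without any
  restricted data.

## Worked example

How much would averaging repeat administrations of an online 24-hour
questionnaire improve protein measurement, given published
single-administration attenuation 0.27, two-administration attenuation 0.37
and single-administration correlation with truth 0.40?

```r
library(dietvalid)
extrapolation_table(0.27, 0.37, 0.40, K = 5)
#>   k    lambda       rho lambda_2dp rho_2dp
#> 1 1 0.2700000 0.4000000       0.27    0.40
#> 2 2 0.3700000 0.4682513       0.37    0.47
#> 3 3 0.4221127 0.5001408       0.42    0.50
#> 4 4 0.4540909 0.5187397       0.45    0.52
#> 5 5 0.4757143 0.5309470       0.48    0.53
```

Reading: with five administrations instead of one, the attenuation factor
rises from 0.27 to 0.48 — a true log relative risk of, say, 0.5 would be
estimated near 0.24 instead of 0.14 — and the correlation with true intake
rises from 0.40 to 0.53.  Repetition shrinks only the within-person error
(σ²_w → σ²_w/k); the person-specific bias is untouched, which is why the
gain saturates.

The full simulated analysis lives in `analysis/01_simulate.R` …
`05_subgroups.R` (simulate → biomarker prep → per-nutrient ML fits with
bootstrap CIs → k-repeat tables → subgroup refits), writing its tables
under `results/`.  On the default seed, step 3 estimates the generating
protein attenuation 0.27 as 0.33 (bootstrap 95% CI 0.23–0.44) at n = 160,
and step 5's homogeneous strata agree within sampling error (for example
men 0.28 vs women 0.36).  `run_pipeline()` performs the same steps in one
deterministic call from a config list or JSON file.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the published single- and two-administration metrics of
each nutrient (protein, potassium, total sugars, total energy), the
predicted attenuation factors and correlations with true intake for 2–5
repeat administrations via the closed-form variance-ratio solve, and writes
them as JSON keyed by target id.
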