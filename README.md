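# ccwrisk

Target trial emulation for hospital observational data with competing risks:
the **clone–censor–weight** design with a treatment grace period, analysed
through a three-state model with constant cause-specific hazards.

## Who this is for

Epidemiologists and biostatisticians estimating the effect of an in-hospital
treatment from registry data in which every admission ends in one of two
absorbing states — in-hospital death or discharge alive — and treatment, when
given, starts some days after admission. Such data invite three biases at
once: immortal time bias (classifying patients by eventually received
treatment), confounding by indication (sicker patients get treated), and
competing-risks bias (treating discharge as censoring inflates the apparent
mortality). `ccwrisk` addresses all three in one pipeline.

## The method

Each patient is cloned at admission into both strategy arms ("initiate
within the grace period of *g* days" vs "do not"). Clones are artificially
censored when the observed data deviate from their arm's strategy during the
grace period, and the selection this induces is undone with inverse
probability of censoring weights from per-arm models of the daily censoring
process on baseline covariates. Outcomes follow a three-state model with
constant daily cause-specific hazards λ₀₂, λ₀₃ (untreated → death,
discharge) and λ₁₂, λ₁₃ (treated), estimated by weighted pooled logistic
regression over person-days. Under constant hazards the cumulative incidence
of cause *j* in arm *i* is closed-form,

    CIF_ij(t) = (λ_ij / λ_i) · (1 − exp(−λ_i t)),   λ_i = λ_i2 + λ_i3,

from which the package derives mortality risks MR_i = λ_i2/λ_i, risk
differences and ratios for both causes, cause-specific hazard ratios
λ₁ⱼ/λ₀ⱼ, and expected lengths of stay 1/λ_i. Weighted Nelson–Aalen and
Aalen–Johansen estimators provide a non-parametric check, a naive
Kaplan–Meier comparator quantifies the competing-risks bias, and percentile
confidence intervals come from a patient-level bootstrap that refits the
whole pipeline in every replicate. A discrete-time cohort simulator with
confounded treatment initiation supplies ground truth for validation.

## Worked example

```r
library(ccwrisk)

cohort <- simulate_cohort(simulation_config(n = 618), seed = 2026)
report <- run_pipeline(cohort, B = 500, seed = 2027)
print(report)
```

```
== clone-censor-weight emulation report (seed 2027) ==
        arm followed artificially_censored
1   treated      397                   221
2 untreated      282                   336
<ccw_hazards> constant daily cause-specific rates
  untreated: death 0.0109, discharge 0.1237
  treated:   death 0.0092, discharge 0.1166
<ccw_effects> constant-hazards treatment effect measures (tau = 60 days)
  mortality risk:  treated 0.073, untreated 0.081  (difference -0.008, ratio 0.904)
  discharge risk:  treated 0.927, untreated 0.919  (difference 0.008, ratio 1.008)
  hazard ratios:   death 0.846, discharge 0.943
  length of stay:  treated 7.947 d, untreated 7.430 d  (difference 0.517 d)
bootstrap percentile intervals (B = 500, 0 failed):
                 statistic estimate  ci_low ci_high
1             rd_death_tau -0.00774 -0.0550  0.0323
...
grace-period sensitivity:
  grace_period_days rd_death_tau rd_discharge_tau ...
```

Reading the output: of 618 admissions, 397 clones are followed in the
treated arm (treated within the grace period, plus early terminal events
that legitimately feed both arms) and 221 are censored for never starting in
time; mirrored counts in the untreated arm. The four constant hazards imply
a 60-day mortality risk of 7.3% treated versus 8.1% untreated — a risk
difference of −0.008 whose bootstrap interval comfortably contains zero, as
it should here: the generator's true death hazard ratio is 0.8 on a low
baseline mortality, so at n = 618 the effect is not distinguishable from
null. Mean length of stay is close to 8 days in both arms (the generator's
1/λ). The sensitivity block repeats the analysis with one- and three-day
grace periods.

The same pipeline runs from a shell:

```sh
Rscript inst/scripts/ccwrisk-cli.R simulate --n 618 --seed 1 --out cohort.csv
Rscript inst/scripts/ccwrisk-cli.R report --input cohort.csv --boot 500 --out-dir results/
```

## Validation suite

`tests/testthat/test-acceptance.R` holds the end-to-end statistical checks:
exact worked effect-measure contrasts; the algebraic conservation
CIF_death + CIF_discharge = 1 − exp(−λt); equality of the pooled-logistic
MLE with the weighted occurrence/exposure ratio; recovery of all four
hazards (within Monte-Carlo error) from an unconfounded cohort of 5,000;
the weighting beating the unweighted estimator under strong confounding by
indication in ≈97% of replicates; pointwise dominance of the naive
Kaplan–Meier death curve over the Aalen–Johansen incidence; agreement of
the Aalen–Johansen estimate with the closed-form curves; and bootstrap
seed-stability plus interval coverage over 200 simulated cohorts.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch — simulates
the default 618-admission cohort, emulates, weights, estimates, bootstraps
(B = 500) and reruns the grace-period sensitivity — and writes its JSON
summary to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
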