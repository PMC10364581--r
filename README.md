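# dmburden

Desk-scale estimation of the global burden of diabetes: from noisy
epidemiological inputs to internally consistent prevalence and mortality
estimates, DALYs, risk-attributable burden, and a prevalence forecast to
2050 — with Monte-Carlo draws carried through every stage.

The package is aimed at epidemiologists and biostatisticians who want a
fully testable, self-contained implementation of the burden-of-disease
estimation chain. Real multi-source inputs (vital registration, surveys,
claims) are not redistributable, so `dmburden` ships a synthetic-world
generator with a known truth; every estimator is validated by recovering
that truth under stated noise models.

## What it implements

* **Illness-death model.** Susceptible/case compartments along age:
  `dS/da = -(i+m)S + rC`, `dC/da = iS - (r+m+f)C`, with prevalence
  `p = C/(S+C)` and cause-specific mortality `CSMR = p·f`. Rates are
  piecewise-constant on the age grid and each segment is solved exactly
  with the closed-form 2×2 matrix exponential (`solve_illness_death()`).
  `fit_rates()` recovers incidence, excess mortality and (capped)
  remission from noisy prevalence + CSMR data by penalised weighted least
  squares with bootstrap draws; type 2 = total − type 1 at draw level.
* **Death-type redistribution.** A log-linear regression of the type-2
  share among type-coded deaths on age, sex and obesity prevalence,
  trained only on country-years passing the 50%-coded and 70%-type-2
  filters, splits deaths coded to unspecified diabetes; all under-15
  deaths are type 1; cell totals are conserved exactly.
* **Crosswalks.** Least-trimmed-squares estimation of case-definition
  log-ratios (exactly ⌈0.10·n⌉ pairs trimmed, exhaustive subset search for
  n ≤ 20), delta-method uncertainty inflation, and mean-FPG-to-prevalence
  conversion via the lognormal upper tail above 7 mmol/L.
* **Burden accounting.** YLL = deaths × remaining life expectancy;
  YLD from four sequelae with multiplicative comorbidity correction;
  DALY = YLL + YLD per draw; standard population from locations above 5
  million people; age-standardised rates per 100 000.
* **Risk attribution.** PAF = (E[RR] − 1)/E[RR] with TMREL-normalised
  piecewise-linear RR curves over a 16-risk registry; draw-wise
  attributable DALYs; independence aggregation 1 − Π(1 − PAF).
* **Forecasting.** logit(prevalence) = β₁·covariate + α per
  location-age-sex stratum (SDI for type 1, mean BMI for type 2), REML
  random intercepts, rate-space intercept shift so 2021 matches the
  estimate exactly, and case counts from forecast population.

See `vignettes/methods.Rmd` for the model details, numerical conventions
and design decisions.

## Worked example

```r
library(dmburden)

## a 5-location world, 20 age groups, 1990-2021, 100 draws
res <- run_pipeline(world_config(seed = 1))

## global DALYs at 2021 with 95% uncertainty interval
summarise_draws(ds_aggregate(res$burden$daly))
#> # A tibble: 1 x 4
#>   location_id     mean    lower    upper
#>         <int>    <dbl>    <dbl>    <dbl>
#> 1           0 3013861. 2986704. 3041396.

## definition crosswalk recovered from contaminated pairs
res$ratios[, c("definition", "log_ratio", "se")]
#> # A tibble: 4 x 3
#>   definition log_ratio     se
#>   <chr>          <dbl>  <dbl>
#> 1 fpg            0     0
#> 2 hba1c         -0.127 0.0122
#> 3 ogtt           0.150 0.0158
#> 4 ppg            0.212 0.0209

## forecasting: fitted slope on mean BMI (logit units per kg/m^2)
res$forecast$model_type2
#> <forecast_model: beta1 = 0.05634 per unit BMI, 200 strata (random intercepts)>
```

The DALY summary is the draw-based global total (the mean and the
2.5th/97.5th percentiles across 100 draws). The crosswalk table shows the
trimmed log-ratio estimates against the true values ln(0.9) = −0.105,
ln(1.15) = 0.140, ln(1.25) = 0.223 used to bias the simulated datapoints.
The fitted BMI slope sits near the generating incidence-on-BMI effect
(0.06/kg/m²); the world's prevalence is not exactly logit-linear in BMI,
so exact equality is not expected.

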