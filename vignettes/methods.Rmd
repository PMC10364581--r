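---
title: "Methods: illness-death modelling, burden accounting and forecasting in dmburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: illness-death modelling, burden accounting and forecasting in dmburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmburden)
```

`dmburden` re-implements, at desk scale, the estimation chain used in
global burden-of-disease work on diabetes: noisy multi-definition
prevalence data and partially type-coded death data go in; internally
consistent prevalence, incidence and mortality estimates, DALYs,
risk-attributable burden, and a prevalence forecast to 2050 come out, with
Monte-Carlo draws carried through every stage. Because the real inputs
(vital registration, surveys, claims) are not redistributable, the package
ships a synthetic-world generator with a known truth, and every estimator
is validated by recovering that truth.

## The synthetic world

`make_world()` builds a flat hierarchy of locations (default 5) on 5-year
age groups 0–95+ over 1990–2021, with:

* **True rates.** Type 1 incidence is a childhood-peaked Gaussian curve in
  age; type 2 incidence is zero below age 15, rises sigmoidally with age,
  and scales log-linearly with mean BMI (0.06 per kg/m² by default), so
  prevalence genuinely trends with the covariates. Remission is exactly 0
  for type 1 and a constant 0.004/yr for type 2, below the 1%/yr cap
  enforced downstream. Excess mortality rises linearly with age;
  background mortality is Gompertz.
* **Consistency by construction.** For each location–sex–year stratum the
  per-type prevalence is the exact solution of the illness-death equations
  for that type's rates. Totals are defined additively: total incidence,
  remission, excess mortality, prevalence and CSMR are the type 1 + type 2
  sums. (Solving the summed rates would not give summed prevalences; the
  additive convention is the one the estimation chain actually needs, and
  the tests assert both per-type exactness and additivity.)
* **Observation models.** Survey datapoints are binomial draws at an
  effective sample size of $0.25/\text{noise}^2$, so the `noise` argument
  is the standard error at prevalence 0.5; the reported SE is the binomial
  SE. Alternate case definitions (HbA1c, OGTT, PPG) are biased by known
  log-ratios; gross outliers multiply the truth by 0.2 or 5 to create the
  contamination regime the trimmed estimator targets. Death data are coded
  to type 1/type 2/unspecified, conserving cell totals exactly, with a
  configurable (optionally per-location) unspecified fraction defaulting
  to 0.55 — more than half of deaths lack a type code.

What the generator does *not* emulate: real survey design effects,
claims-specific biases, a nested location hierarchy, migration, or
cohort effects. Passing tests therefore demonstrate internal correctness
and statistical recovery under the stated noise models, not performance on
real data.

## The illness-death model

`solve_illness_death()` integrates, along age for one birth cohort at a
fixed calendar year (a period approximation, consistent with
cross-sectional estimation),

$$\frac{dS}{da} = -(i+m)S + rC, \qquad
  \frac{dC}{da} = iS - (r+m+f)C,$$

with prevalence $p = C/(S+C)$ and cause-specific mortality
$\text{CSMR} = p\,f$. Rates are piecewise-constant on the age grid, so
each segment is a constant-coefficient linear system and is propagated
with the closed-form 2×2 matrix exponential — the solution is exact per
segment rather than meeting a step-refinement tolerance. The off-diagonal
entries ($i$, $r$) are non-negative, so the eigenvalues are real; the
implementation is written via $\phi = \operatorname{expm1}(2\delta)/2\delta$
so the equal-eigenvalue limit is smooth. Group-level prevalence is
reported at the age-group midpoint (the open-ended top group uses start +
2.5 years and a 5-year integration width). Tests compare against an
independent fine-grid Euler oracle and closed forms
($p = 1 - e^{-ia}$ when $r = f = 0$; steady state $i/(i+r)$ when $f=0$).

`fit_rates()` estimates the age curves from data as a single-level
penalised fit (a stand-in for a full hierarchical cascade): weighted least
squares on prevalence datapoints and the CSMR series, plus a smoothness
penalty on squared second differences of log-rate values at knots (one
knot per two age groups, linear interpolation in between). Bounds are
enforced in the log parameterisation: all rates positive, remission capped
at 0.01/yr for total diabetes and fixed at 0 for type 1. Background
mortality enters as all-cause minus observed diabetes CSMR, floored at
1e-6/yr. Uncertainty is a nonparametric bootstrap of the prevalence
datapoints (default 100 replicates, matching the draw count), implemented
as multinomial reweighting with refits warm-started at the point estimate.
Numerical choices: L-BFGS-B, convergence `factr = 1e9`, iteration caps of
200 (point fit) and 40 (bootstrap refits; 15 in the pipeline, where the
warm start makes further iterations immaterial). Type 2 is obtained by
draw-level subtraction of type 1 from total, floored at zero, with all
under-15 prevalence assigned to type 1 first; clamped draws are counted in
a diagnostic attribute.

Identifiability caveat: with remission free, incidence and remission are
only weakly separated by cross-sectional prevalence plus CSMR; the cap and
the smoothness penalty regularise this, and the recovery tests use the
type-1-like configuration (remission known) to check incidence and excess
mortality to 5% on interior age groups.

## Death-type redistribution

More than half of simulated diabetes deaths carry no type code. The
type-split model is trained only on country-years where (a) more than 50%
of diabetes deaths are type-coded and (b) at least 70% of type-specific
deaths over age 25 are coded type 2. "Log-linear" is implemented literally
as a linear model of log(type-2 share among coded deaths) on age, sex, and
obesity prevalence. Age enters as age-group indicators rather than a
linear term: the share saturates towards 1 at old ages, and forcing a
line through that pattern in log space leaves an aggregate bias that the
recovery requirement below exposes. Predictions apply a Duan smearing
factor (the mean of exponentiated residuals) to undo the retransformation
bias of exponentiating a fitted log mean, then clamp to [0, 1]; a
logit-link variant sits behind `link = "logit"`. Unspecified deaths in
each cell are split by the predicted share; all under-15 deaths go to
type 1; cell totals are conserved exactly (fractional deaths are allowed,
since YLLs are real-valued). The seeded recovery test requires the global
type-2 death share to be recovered within 2 percentage points.

## Crosswalks

Alternate-definition datapoints are mapped to the FPG ≥ 7 mmol/L reference
by a least-trimmed-squares location estimate of the paired log-ratios:
exactly $\lceil 0.10\,n \rceil$ pairs are excluded, chosen to minimise the
retained sum of squared residuals — by exhaustive subset search for
$n \le 20$ and by concentration steps with 20 random restarts above that.
Adjustment multiplies by $e^{-\hat\beta}$ and inflates uncertainty by the
delta method in log space, so the *relative* SE never decreases (the
absolute SE can shrink when the adjustment scales a value down; the
relative-scale guarantee is the meaningful one and is the one tested).
Mean-FPG-only reports convert to prevalence as the upper-tail probability
above the threshold under a lognormal population distribution
(moment-matched to the reported mean and SD), with a normal option; the
two-family choice is a deliberate simplification of ensemble-distribution
modelling.

## Burden accounting

YLL = deaths × remaining life expectancy at the age-group midpoint, from a
synthetic standard life table (the real reference life table is not
reproducible here). YLDs use four sequelae — neuropathy, diabetic foot,
lower limb amputation, vision loss due to retinopathy — treated as
mutually exclusive partitions of prevalent cases with synthetic disability
weights (0.133, 0.165, 0.164, 0.184) and splits (0.25, 0.06, 0.02, 0.04).
Comorbidity with background disability $b$ is corrected multiplicatively
under independence: the combined disability $1-(1-\text{DW})(1-b)$ is
allocated to the sequela in proportion DW/(DW+b), which reduces YLDs
whenever $b>0$ and is exactly the hand-checkable two-condition formula
(DWs 0.2 and 0.3 combine to 0.44, of which 0.176 is the first condition's
share). DALY = YLL + YLD draw-wise. The standard population is the
unweighted mean of age-proportional distributions of locations above 5
million people; age-standardised rates are the weighted sums.

## Risk attribution

Relative-risk curves are piecewise-linear on a stated exposure grid
(regularised-spline fitting is out of scope; piecewise linearity keeps the
PAF integral exactly hand-checkable). Curves are normalised at the TMREL —
a point, or an interval averaged uniformly — and

$$\text{PAF} = \frac{\int p(x)\,\text{RR}(x)\,dx - 1}
                    {\int p(x)\,\text{RR}(x)\,dx}$$

with trapezoid integration (sums for categorical exposures). The 16-risk
registry attaches the two air-temperature risks to both diabetes types and
everything else to type 2 only. Curve uncertainty enters draws as a single
lognormal scale on the log-RR curve. Risks combine as
$1-\prod_j(1-\text{PAF}_j)$ — an explicit independence approximation, with
no mediation adjustment, so the combined figure is not claimed to
reproduce mediation-adjusted published values. PAF percentage change
between years is computed draw-wise, then summarised (summary-level
arithmetic on rounded means gives visibly different answers and is not
used).

## Forecasting

The forecast model is logit-prevalence on a single covariate with a random
intercept per location–age–sex stratum:
$E[\operatorname{logit} Y_{l,a,s,y}] = \beta_1 x_{l,y} + \alpha_{l,a,s}$,
with SDI as the covariate for type 1 and mean BMI for type 2. Estimation
is REML via `lme4` by default; a fixed-effects (one intercept per stratum)
variant is available because the mean structure alone does not dictate the
estimator, and the noiseless-recovery test uses it for exactness.
Prevalence is clamped to [1e-6, 1-1e-6] before the logit (zero-prevalence
cells exist at young ages). Projections are intercept-shifted in natural
(rate) space so the 2021 value equals the 2021 estimate exactly, clamping
to [0, 1] with a counted warning. Case counts are prevalence × forecast
population; the total forecast is defined as type 1 + type 2 per cell.
In the pipeline, the historical series fed to the forecast fit is the
world's per-year true prevalence (standing in for a previously estimated
series), while the anchor is the pipeline's own fitted 2021 estimate;
covariate and population forecasts are inputs, extrapolated from their
logit-linear location trends and a 1%/yr growth assumption respectively.

## Uncertainty and presentation

Everything downstream of estimation is a `drawset`: a demographic key
table plus an n-cells × 100 draw matrix. Draws are normal in a declared
transformed space (log for rates and counts, logit for proportions);
summaries are the mean and the 2.5th/97.5th percentiles with
linear-interpolation quantiles (type 7) — on draws 1…100 the interval is
exactly (3.475, 97.525), which is frozen in a test. Counts print to three
significant figures; rates and percentages to one decimal, rounding half
away from zero. Any operation that would change the draw count fails with
an alignment error.

## Problem sizes and defaults

The shipped configuration — 5 locations, 20 age groups, two sexes,
1990–2021, 100 draws, survey noise 0.02, 8% gross-outlier rate, 55%
unspecified deaths — is the scale at which the full pipeline and its
recovery properties are exercised; `run_pipeline()` completes in a few
minutes on one core at this size. Fit-quality tolerances (5% rate
recovery on interior age groups, 10% forecast-slope recovery, 2-point
death-share recovery) were chosen as what the stated noise levels support,
and the tests hold the generator to them.

## Known limitations

* No hierarchical borrowing across locations; each stratum is fitted
  independently.
* Incidence/remission confounding in the cross-sectional fit (above).
* Combined PAFs ignore mediation and risk–risk correlation.
* The covariate and population forecasts are mechanical extrapolations,
  not modelled futures.
* COVID-era shocks, gestational and monogenic diabetes are out of scope.
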