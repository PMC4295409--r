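---
title: "Estimating and projecting complete cancer prevalence by phase of care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and projecting complete cancer prevalence by phase of care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevmod)
```

## The problem

Cancer registries observe diagnoses and deaths over a finite window, yet
health-service planning needs the *complete prevalence* — everyone alive
today who was ever diagnosed — and its projection a decade ahead, broken
down by where survivors sit in the care trajectory. prevmod implements
the registry-based estimation chain for this problem, developed here for
first-primary female breast cancer in a closed 18–84 population observed
1972–2007 and projected to 2017, but parameterised throughout by
`analysis_config()`.

The chain has four stages, each behind its own function surface:

1. **Incidence.** Diagnosis counts per single year of age and calendar
   year are modelled by Poisson regression with a log person-years
   offset and polynomial age and birth-cohort effects (period degree 0:
   drift is absorbed by the cohort terms, which also sidesteps the
   classic age-period-cohort identification problem). Nine candidate
   models `APC101 … APC303` (the digits are the age/period/cohort
   polynomial degrees) are ranked by the likelihood-ratio statistic
   against the saturated model; the cubic age + cubic cohort model is
   the default projection model. The fitted polynomial extends naturally
   before and after the window because the cohort index continues as
   `year − age`.
2. **Net survival.** Relative survival is tabulated with the Pohar Perme
   inverse-expected-survival-weighted actuarial estimator over annual
   intervals, with the cohort approach (interval *j* uses only cases
   whose potential follow-up reaches *j*, so administrative censoring
   never cuts an interval). A mixture cure model
   `RS(t) = c + (1 − c)·exp(−(λt)^γ)` is then fitted per age group to
   the tabulation by inverse-variance weighted least squares, with a
   linear trend on `logit c` and on `log λ` across diagnosis years.
   Before the observation window the parameters are frozen at their
   first-year values; after it the linear trends continue.
3. **Prevalence and mortality.** The discrete transition identity
   `N(a, t, d) = I(a−d, t−d)·PY(a−d, t−d)·RS(d; g(a−d), t−d)·S_E(a−d, t−d, d)`
   convolves expected diagnoses with net survival and expected
   (life-table) survival, giving the expected number of people of
   attained age `a` alive at mid-year `t` who were diagnosed `d`
   completed years earlier. Expected cancer deaths accumulate the
   excess-death decrements `S_E(d)·[RS(d) − RS(d+1)]` of every cohort,
   and comparing them with observed cancer deaths validates incidence
   and survival jointly.
4. **Phases of care.** Each year's prevalence is partitioned into
   initial care (first 12 months, excluding those dying of the cancer
   within the year), post-treatment monitoring (durations 1–9),
   long-term survivorship (10+), and the last year of life (the next
   year's expected cancer deaths, allocated across age/duration strata
   proportionally to their modelled excess deaths). The proportions of
   monitoring and long-term members presenting a subsequent metastasis
   or second primary in a reference year — and surviving a year after
   it — are then applied to the projected parent phases to form the
   treatment-for-metastases/second-cancer sub-phase.

## Timing conventions

Everything is discretised to integer calendar years with mid-year
timing: diagnoses sit at mid-year, the population denominators are
mid-year counts, durations run mid-year to mid-year, and a person counts
as prevalent in year `t` exactly when their death year exceeds `t`.
Under this convention the discrete annual convolution replaces the
continuous transition differential equations with second-order
discretisation error, and the excess-death decrement at duration `d` of
a cohort diagnosed in `t − d` is a death registered in calendar year
`t + 1`; the mortality series is indexed by the year deaths are
registered. One visible consequence: cases dying in their diagnosis year
never enter the prevalence counts, and the survival tabulation assigns
them to interval 1.

Expected survival always runs along the diagnosis-cohort diagonal of the
life table — age and calendar year advance together — and the life table
is extended beyond its grid by freezing the edge values (first/last
year, highest age). The net-survival age group of a cohort is fixed by
age at diagnosis, not attained age.

## Backcasting and population projection

A person aged 84 in the first reported year could have been diagnosed
66 years earlier, so incidence is evaluated back to
`obs_year_min − (age_max − age_min)` (1906 under the defaults) from the
fitted polynomial, and person-years before the observed window are
reconstructed by reverse survival along cohort diagonals with the frozen
life table (the exact mirror of the forward cohort-component projection,
which holds the youngest-age inflow and the last observed year's
mortality constant). Prevalence in the first 18 reported years leans
most heavily on these backcasts and is flagged `backcast_sensitive`.
Projection-year proportions use the projected open population rather
than a closed cohort, and prevalence proportions are always per 100,000
of the 18–84 population.

## The synthetic registry and what passing tests show

Because the registry extract behind the original analysis is not
distributable, `simulate_registry()` generates one with known ground
truth, emulating exactly the structure the analysis assumes: Poisson
cell counts from a log-linear age+cohort rate (on the same centred
covariates the model uses), mixture cure net survival with a logit-linear
cure trend frozen before the window, Gompertz background mortality with
a secular improvement trend, and a demographically self-consistent
population built from a growing birth series so that the analysis's
reverse-survival backcast recovers the truth exactly. Cancer and
background death years are discretised so that the probability of being
alive `d` completed years after diagnosis is *exactly* `RS(d)·S_E(d)` —
the oracle comparisons therefore measure estimation error, not
discretisation slack.

Default scale and parameter choices, fixed once:

* ~90,000 diagnoses inside the 36-year window (the scale of the original
  cohort), from an 18–84 population growing from ≈1.4M to ≈2.2M and a
  2007 crude rate of ≈175 per 100,000 at these ages;
* cure fractions around 0.5–0.65 at the 1990 reference year with logit
  slopes of 0.025–0.03 per year (five-year net survival ≈0.8 by the
  2000s), Weibull scales 0.18–0.25 per year and shapes 0.9–1.1;
* annual metastasis and second-primary hazards of 0.015 and 0.008 among
  survivors, chosen so the annual sub-phase proportions sit near the
  ~2%/1.5% magnitudes that drive the sub-phase projection. A constant
  hazard cannot simultaneously reproduce a ~15% cumulative metastatic
  fraction and ~2% annual event proportions (real metastasis risk is
  concentrated early after diagnosis); the defaults favour the annual
  proportions, which are what the projection consumes.

The generator deliberately omits screening-induced incidence bumps,
period effects (e.g. hormone-therapy shocks) and age–period
interactions, and second primaries do not alter a case's survival law.
Passing the oracle tests therefore shows the estimation chain is
faithful *given the modelled structure*; it cannot show robustness to
structural violations a real registry may contain.

## Numerical choices

* APC covariates are centred and scaled — `(age − 50)/10`,
  `(cohort − 1940)/10` — before polynomial expansion; raw cubic years
  are numerically ill-conditioned. Coefficients are reported on that
  scale and the transform is stored in the fit. Cells with zero
  person-years are dropped, not imputed.
* The cure fit runs `nlminb` from three starting points (the
  long-duration plateau seeds the cure level) inside generous bounds,
  with a Nelder–Mead polish if needed; standard errors come from the
  Gauss–Newton approximation. Cure fractions within 0.005 of 0 or 1 at
  an observed period midpoint are flagged as boundary solutions.
  Weights are inverse squared standard errors floored at the smallest
  positive value; an all-zero `se` column means unweighted fitting.
* Survival strata stop tabulating at the first interval with fewer than
  `min_at_risk` (default 10) unweighted cases, and at
  `max_follow_up_intervals` (default 25) annual intervals.
* Sub-phase counts are rounded per age-group cell and subtracted from
  their parent phases, so totals are conserved exactly despite rounding.
* When the death allocation would exceed a stratum's prevalence (possible
  only with an externally supplied deaths series), it is clipped at the
  stratum's prevalence with a warning.

## Problem sizes used by the test-suite experiments

The packaged experiments run the full default scenario once (~90k window
cases; a few seconds end to end) for the oracle, mortality and
conservation checks; parameter-recovery replicates for the cure model
use 50 synthetic tabulations with binomial-scale noise, matching the
two-step design in which the cure model's input contract is the
tabulation, not the case list. Reduced registries (1/20 scale) back the
structural and determinism tests.

## Known limitations

* No uncertainty intervals are produced for projections; the transition
  convolution propagates point estimates only. (Bootstrap over the
  simulate–refit loop is possible but not part of the tested surface.)
* The mixture cure parameterisation (Weibull non-cured survival,
  logit-linear cure trend, log-linear scale trend) is one canonical
  choice among several; it is isolated behind `cure_fit`/`predict`
  so an exponential variant is a small change.
* Ages 85+ are carried in the population table but excluded from all
  estimates; complete prevalence is correspondingly understated for the
  oldest survivors.
* Cause of death must be recorded for every dead case; the last-year-of-
  life phase does not guess at unknown causes, it errors.
* The annual time grid cannot adjudicate event timing finer than a year
  except where `days_since_dx` accompanies an event notification (used
  by the 120-day metastasis lag rule).

## A worked run

```{r, eval = FALSE}
cfg <- analysis_config()
res <- run_pipeline(cfg, out_dir = "prevmod-out", params = sim_params())
summary(res$surface)            # prevalence and per-100k by year
res$selection                   # the nine-model LRS ranking
print(res$cure)                 # cure fractions and trends by age group
attr(res$validation, "mard")    # mortality validation summary
res$report$table2               # phase-of-care table for the final year
```
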