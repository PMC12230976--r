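---
title: "Migration-status mortality analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migration-status mortality analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Internal migrants — people who leave their region of birth — are often found
to have lower mortality than those who stay, mirroring the migrant mortality
advantage documented for international migrants. Register data make it
possible to follow every individual's region of residence over decades, to
separate *stayers* (never observed outside the birth region), *leavers*
(living elsewhere at death or at the end of follow-up) and *returnees* (back
in the birth region at death or at the end of follow-up), and to ask whether
movers' lower mortality reflects health selection into migration or negative
selection of return migrants (the "salmon bias").

Because genuine population registers cannot be redistributed, `migmort`
couples the full analysis pipeline to a synthetic register generator that
reproduces the statistical structure such an analysis must cope with:
observation only at census years followed by annual registration (which left-
and interval-censors ages at migration), region- and period-structured
mortality, status-dependent mortality with age interactions, and a
cause-of-death mix with a small ill-defined fraction. All pipeline code is
agnostic about whether its input came from the generator or from real
register extracts with the same layout.

## The generator and what it emulates

`sim_config()` / `simulate_population()` evolve each person in discrete
annual steps from birth. Within a year the person may move first (out of the
birth region, back to it, or onward between two non-birth regions), then
faces a death draw with probability $1 - \exp(-r)$,
$$\log r = \text{baseline}(x) + \beta_r + \beta_t + \beta_m(x),$$
where $x$ is age, $\beta_r$ a birth-region offset, $\beta_t$ a calendar-year
offset, and $\beta_m$ the effect of the *current latent state* (stayer until
the first move, leaver while away, returnee after a return). The December-31
region defines that year's residence snapshot; a person who dies keeps the
region they lived in during the death year.

Defaults (chosen once, as plausible values for a high-income national
register; they are the package's standard study conditions):

* 21 birth regions; follow-up 1970–2018; birth cohorts 1905–1998; equal sex
  ratio.
* Gompertz baseline $2\times 10^{-5} e^{0.095x}$ (about $1.3\times10^{-4}$
  at age 20, 0.1 at age 90).
* Region offsets: a linear gradient of ±0.15 log units (sum zero),
  emulating a persistent regional mortality divide; year offsets +0.25 to
  −0.25 (sum zero), emulating secular improvement. Sum-to-zero generator
  effects mirror the identifiability constraints of the estimation model.
* Out-migration hazard piecewise-constant in age (0.010 below 17, 0.030 at
  17–29, 0.008 at 30–59, 0.004 at 60+): migration peaks at study/work ages,
  children move with their families. Return hazard 0.01/yr, onward moves
  0.005/yr.
* Status effects: leaver −0.15, returnee −0.25 log units (a mover
  advantage); constants by default, functions of age if desired.
* Six cause groups (neoplasms, dementia/Alzheimer's, circulatory,
  respiratory, alcohol-related, external) with a smooth age-varying mix —
  external and alcohol-related causes dominate young-adult deaths,
  circulatory disease and neoplasms midlife and old age, dementia the oldest
  ages — and a 2% chance that a death's cause is recorded as ill-defined.

Mortality draws begin at the horizon start: the sample is conditioned on
being alive in 1970, and earlier years simulate residential mobility only.
This is what generates left censoring — for cohorts born long before 1970
the first move often predates the first residence observation.

What the generator does *not* emulate: realistic geography or
region-specific population sizes, emigration, within-region moves, household
structure, socioeconomic covariates, or cohort effects beyond the
period-by-age structure. Tests that pass on generated data therefore
demonstrate the estimators' internal consistency under the stated model
family, not robustness to every feature of real registers.

`apply_observation_scheme()` restricts residence snapshots to the observed
years — by default the census years 1970/1975/1980/1985 and then every year
1987–2018 — while birth region and vital events stay fully known, as in
register data.

## Classification and censored migration ages

`classify_histories()` applies the retrospective definitions: stayer if
never observed outside the birth region; otherwise leaver or returnee
according to the last relevant observation (Dec 31 of the final year, or the
region in the year of death, which the death record supplies). Leavers are
banded by age at first out-migration (<17, 17–29, 30–59, ≥60) and returnees
by age at return (<30, 30–59, ≥60; a four-band split is available for
descriptive tables).

A move observed between snapshots in years $y_{prev}$ (origin state) and
$y_{out}$ (destination state) happened in a calendar year in
$(y_{prev}, y_{out}]$, so at annual granularity the age at the event lies in
$[y_{prev}-b+1,\; y_{out}-b+1)$ for birth year $b$; a width-one interval is
exact. When the first observation is already outside the birth region the
age is left-censored on $[1, \text{first-observation age}+1)$ — a person
cannot move before age 1.

`fit_event_age_model()` treats the event age as a piecewise-constant hazard
on the age bands 0–16 / 17–29 / 30–59 / 60+, estimated by maximum likelihood
from exact and interval-censored records, stratified by sex and birth-cohort
band. Two numerical points matter:

* **Right truncation.** Only people whose move was observed enter the
  record set, so each contribution is conditional:
  $P(L \le T < H) / P(1 \le T < C)$, where $C$ is the age at the person's
  last observation. Ignoring this inflates late-age hazards severely (young
  cohorts can only contribute early moves).
* **Log-space evaluation.** Interval probabilities are computed as
  differences of log-survival via `log1p`; naive differences of survival
  probabilities underflow for extreme hazard values and create spurious
  optima. Log-hazards are box-constrained to $[\log 10^{-5}, \log 0.95]$.

`impute_event_ages()` draws each censored age from the fitted distribution
truncated to its bounds (single seeded draw; multiple-imputation variance
propagation is intentionally out of scope — sensitivity is assessed by
re-running with different seeds). Degenerate intervals are forced; intervals
with zero model mass fall back to their midpoint with an audit count. The
hazard family is pluggable in the sense that the model object only needs to
supply band boundaries and log hazards.

## Exposure attribution: the central design choice

The exposure table (`build_exposure_table()`) aggregates person-years and
deaths by 3-year age group (20–22, …, 92–94; midpoints 21.5, …, 93.5),
calendar year, sex, birth region and migration status, ages 20–95, with the
death year contributing 0.5 person-years (the within-year timing convention
is configurable).

How to attribute a mover's person-years is the one genuinely open design
question, and the naive answer is wrong in a subtle way. If each person's
entire exposure is booked to their final status, mover rates are biased
downward even when no status effect exists: a leaver who would have died
during a spell back in the birth region would have been classified a
returnee, so such deaths can never appear in the leaver's numerator although
the corresponding person-years sit in the denominator. No truncation rule
applied to final-status exposure can repair this, because the death itself
determines the classification.

`migmort` therefore attributes each person-year to the *state occupied that
year*:

* years before the (observed or imputed) first out-migration, and all years
  of never-movers, are stayer exposure;
* years outside the birth region are leaver exposure, banded by age at
  first out-migration;
* years in the birth region after a return are returnee exposure, banded by
  the age at the return that opened the spell (for a classified returnee's
  final spell, the imputed age at final return).

Deaths attributed this way coincide *exactly* with the retrospective
classification — a death outside the birth region is by definition a leaver
death, a death in the birth region after a return is a returnee death — so
death counts and person-years refer to the same risk sets, and under a null
status effect all status-specific rates agree (this is verified by a
chi-square homogeneity property test and by the degenerate-limit acceptance
test). Between observation years, residence is reconstructed by carrying the
next observation backward (the death-year region counts as an observation);
this is exact under annual observation and an approximation across census
gaps.

Consequences worth knowing:

* "Stayer" exposure includes movers' pre-move years — the stayer schedule
  is the mortality of people *who have not (yet) left*, matching the
  definition "never observed outside the birth region" applied year by year.
* Structural zeros hold by construction: a band defined by moving at 60+
  cannot contribute exposure or deaths below age 60 (`check_structural_zeros()`
  asserts this). The youngest returnee band is modeled only up to the last
  full age group below 77, the oldest age such a career can reach within the
  follow-up window; later person-years are dropped with an audit count.
* Person-years are conserved: tabulated exposure equals in-range alive time
  minus the documented cap drops, exactly.

Ill-defined causes of death are redistributed proportionally to the six
named groups within strata of 5-year period, 5-year age group and sex
(`redistribute_illdefined()`); strata without named-cause deaths fall back
to adjacent age strata, then to the sex-period margin. Per-stratum death
totals are conserved to floating-point accuracy; cause columns become
non-integer, which the negative-binomial fitter accepts.

## The mortality model

`fit_mortality_gam()` fits, separately by sex and (optionally) cause,
$$D_{x,t,r,m} \sim \text{NegBin}(m_{x,t,r,m} E_{x,t,r,m},\ \theta),\qquad
\log m_{x,t,r,m} = \beta_r + \beta_t + \beta_m + s_m(x),$$
with person-years as offset, categorical calendar year (a smooth year term
is a config option), and one penalized cubic-regression-spline smooth of age
per status (basis size 10, reduced automatically when a status has fewer
distinct midpoints), each expressed as a deviation from the status intercept
and centred for identifiability. Fitting is delegated to mgcv (`gam`, or
`bam` with fast REML beyond 20,000 rows); smoothing parameters are selected
by REML and $\theta$ is estimated alongside. A Poisson family and a fixed
$\theta$ are available, which the tests use to check the fitter against
closed-form and independently coded Newton solutions. mgcv centres each
by-status smooth over that status's data rows; on a balanced design this
equals centring over the distinct age midpoints.

Cause-specific fits first restrict the age domain to the contiguous hull of
age groups holding at least 0.5% of the cause's deaths or at least 1000
deaths (`restrict_cause_ages()`), so that spline bases are not asked to
describe ages with essentially no events.

`predict_log_rate()` evaluates the linear predictor with delta-method
standard errors; requests below a band's lower age bound return an explicit
structural-zero result rather than an extrapolation.

## Marginal rates, ratios, life tables, decomposition

`average_marginal_rates()` predicts the rate for every combination of birth
region and calendar year seen in the fit and averages on the rate scale
(equal weights; exposure weighting is a documented alternative), per status
and age midpoint. Uncertainty is by posterior simulation of the
coefficients: draws from $N(\hat\beta, V_{\hat\beta})$ (mgcv's Bayesian
covariance), 5th/95th percentiles of the recomputed averages form a 90%
band. `rate_ratios()` puts the stayer rate in the numerator — ratios above 1
mean lower mortality for the comparison group — and forms percentile bounds
draw-wise, never by dividing bounds.

`build_partial_life_table()` converts a marginal schedule into a grouped
life table on 20–95 with $_nq_x = n\,{}_nm_x / (1 + (n - {}_na_x)\,{}_nm_x)$,
$_na_x = n/2$ (adult ages only), radix 100,000, closed by truncation at 95;
`temporary_expectancy()` returns expected years lived between two boundary
ages. Banded statuses are compared from their band entry age upward — no
rates are invented for structurally empty ages.

`decompose_gap()` attributes the difference in temporary life expectancy
between two cause-specific rate schedules to age × cause cells by the
line-integral method: rates move along the straight line from one schedule
to the other; at each of 1000 midpoint steps the partial derivative of the
functional with respect to each age's all-cause rate is computed by central
finite differences (relative step $10^{-6}$) and multiplied by the cell's
rate change. Because causes enter only through their all-cause sum, one
derivative per age serves all six causes. The residual
$|\sum C - \Delta e|$ is reported and is far below $10^{-6}$ years on smooth
schedules at the default step count; it shrinks roughly quadratically in the
number of steps. `summarize_contributions()` reports per-cause totals and
signed shares of the gap.

## Pipeline, problem sizes, reproducibility

`run_pipeline()` chains the stages (simulate → observe → classify → impute →
aggregate → redistribute → fit → marginalize → life tables → decompose) from
a validated YAML/list configuration (`pipeline_config()`, unknown keys
rejected), writes tidy CSV artifacts plus a JSON manifest carrying the seed
and the MD5 hash of the configuration, and is byte-reproducible given the
same configuration and seed. All randomness is derived from the single
configured seed (simulation, imputation and coefficient draws use distinct
derived seeds). The package's R interface *is* the orchestration layer; the
repository's `scripts/acceptance.R` shows a complete scripted run.

Default problem sizes were chosen as the package's standard demonstration
conditions: the scripted end-to-end run simulates 120,000 individuals under
the full 21-region, 1970–2018 design; estimator-validation tests use
200,000 individuals for point recovery, 50 replicates of 12,000 for
interval coverage (fully observed young cohorts with a deliberately
accelerated Gompertz baseline, so deaths occur at the ages that short
design covers and the model is exactly well-specified), and 50,000 for
imputation-distribution recovery. The
known-truth checks they implement are: a constant status log-effect of
$-\log 2$ is recovered within Monte-Carlo error by the marginal rate ratio;
90% Wald intervals for the status contrast cover the truth at nominal rate;
the Kolmogorov–Smirnov distance between imputed and true migration-age
distributions stays below 0.05 under the census-then-annual scheme.

## Known limitations

* Current-state attribution makes group schedules describe *states*, not
  fixed cohorts of people; descriptive per-person tabulations (one row per
  individual) are available from the classification, but the modeled rates
  deliberately follow the state logic for the reasons above.
* Across census gaps, away/home spells are reconstructed by backward fill
  and one imputed age per defining event; interim spells shorter than an
  observation gap are invisible, so very mobile histories are smoothed.
* Single imputation understates the variance contributed by censored
  migration ages; percentile bands reflect model coefficient uncertainty
  only.
* The piecewise-constant event-age hazard is a four-parameter summary; if
  true migration timing had sharp within-band structure the imputed
  distribution would miss it.
* The generator draws deaths as annual Bernoulli events, so estimated rates
  differ from generator rates by $O(r^2)$ discretization terms — negligible
  below age 90 at realistic levels, and identical across statuses, so
  ratios are unaffected.
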