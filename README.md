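# migmort

Mortality differentials between internal migrants and non-migrants, from
register-style individual histories.

Population registers let one follow every person's region of residence over
decades and compare the mortality of **stayers** (never observed outside
their region of birth), **leavers** (living elsewhere at death or at the end
of follow-up) and **returnees** (back in the birth region at the end),
further split by age at migration. `migmort` implements the full analysis
chain for such data — and, because real registers cannot be shared, a
synthetic register generator with the same statistical structure (census
years followed by annual observation, hence left- and interval-censored
migration ages; region-, period- and status-structured mortality; a
six-group cause-of-death mix with a small ill-defined fraction).

The statistical core is a negative-binomial generalized additive model of
death counts $D_{x,t,r,m}$ on person-years $E_{x,t,r,m}$ in cells of 3-year
age group $x$ × calendar year $t$ × birth region $r$ × migration status $m$:

$$D_{x,t,r,m} \sim \mathrm{NegBin}\left(m_{x,t,r,m} E_{x,t,r,m},\, \theta\right),
\qquad \log m_{x,t,r,m} = \beta_r + \beta_t + \beta_m + s_m(x),$$

with one penalized cubic-spline smooth of age per status (10 basis
functions, sum-to-zero constrained), fit with mgcv, separately by sex and
cause of death. Fitted models are turned into average marginal age-specific
rates (averaging predictions over all region × year combinations), rate
ratios with stayers in the numerator (values above 1 = mover advantage) and
simulation-based 90% percentile bands, partial life tables for ages 20–95
with temporary life expectancies, and line-integral (Horiuchi) age × cause
decompositions of the longevity gaps. Supporting modules handle migration
status classification, imputation of censored ages at migration
(right-truncated interval-censored piecewise-constant-hazard MLE), exposure
aggregation with state-consistent attribution, and proportional
redistribution of ill-defined causes of death. The methods vignette
(`vignettes/methods.Rmd`) documents every model and design choice.

## Worked example

```r
library(migmort)

cfg <- sim_config(n_individuals = 20000, seed = 42)
h   <- apply_observation_scheme(simulate_population(cfg))   # censuses + annual
cl  <- classify_histories(h)
rec <- extract_censoring_records(h, cl)
mod <- lapply(split(rec, rec$event), fit_event_age_model)
imp <- impute_event_ages(rec, mod, seed = 7)
tab <- redistribute_illdefined(
  build_exposure_table(h, assign_status_bands(cl, imp)))

fit <- fit_mortality_gam(tab, sex = "male", status_var = "status_coarse")
sch <- average_marginal_rates(fit, n_draws = 200, seed = 3)
rr  <- rate_ratios(sch)
rr[rr$age_mid %in% c(21.5, 45.5, 75.5), ]
#>      status age_mid ratio lower90 upper90
#> 1    leaver    21.5  1.20   0.923    1.70
#> 9    leaver    45.5  1.20   1.016    1.47
#> 19   leaver    75.5  1.19   1.117    1.28
#> 26 returnee    21.5  1.78   0.947    3.27
#> 34 returnee    45.5  1.59   1.085    2.27
#> 44 returnee    75.5  1.37   1.225    1.57

expectancy_gaps(sch)
#>     status from_age to_age gap_years gap_months gap_pct e_ref e_cmp
#> 1   leaver       20     95     1.422       17.1    2.27 62.74  64.2
#> 2   leaver       50     95     1.294       15.5    3.84 33.67  35.0
#> 3   leaver       80     95     0.600        7.2    6.15  9.76  10.4
#> 4 returnee       20     95     2.657       31.9    4.23 62.74  65.4
#> 5 returnee       50     95     2.331       28.0    6.92 33.67  36.0
#> 6 returnee       80     95     0.925       11.1    9.47  9.76  10.7
```

Ratios above 1 are a mover advantage: the generator's configured effects
(−0.15 log units for leavers while away, −0.25 for returnees after return)
correspond to ratios of about 1.16 and 1.28, and the estimates scatter
around those values — at this small sample size the young-age bands are
wide. The mover advantages cumulate into temporary-life-expectancy gaps of
roughly 1.4 (leavers) and 2.7 (returnees) years between ages 20 and 95. `decompose_by_cause()` then splits such gaps into
age × cause contributions whose columns sum to the total gap.

An end-to-end run from a single YAML/list configuration, with CSV artifacts
and a JSON manifest, is available through `pipeline_config()` /
`run_pipeline()`.

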