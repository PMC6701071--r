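---
title: "Modelling adolescent smoking dynamics and tobacco-control policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adolescent smoking dynamics and tobacco-control policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokedyn)
```

## The model

`smokedyn` simulates the population dynamics of adolescent cigarette smoking
as a deterministic stock-and-flow system. Two school cohorts — middle school
(ages 11–14) and high school (ages 15–18) — are modelled in parallel as an
aging chain: each cohort holds five mutually exclusive stocks,

* never-smokers,
* current experimenters and former experimenters (under 100 lifetime
  cigarettes),
* current smokers and ex-smokers (100+ lifetime cigarettes),

where "current" means any smoking in the past 30 days. Persons move between
stocks through initiation, experimentation pauses and relapse, progression
(crossing the 100-cigarette threshold), cessation, and smoker relapse; every
middle-school stock graduates into the matching high-school stock at 1/(4
years), high-school stocks exit at the same fractional rate, and a cohort
entry flow feeds middle-school never-smokers. Lifetime status is one-way: no
flow reconnects the smoker-side stocks to the experimenter side.

Each behavioural flow is a base hazard (per year) times a product of effect
multipliers, each normalised to 1 at reference conditions anchored at the
start of the simulated window (1992). The feedback structure:

* **Social pressure (reinforcing).** A weighted prevalence index
  $SP = w_{peer}\,p_{cohort} + (1-w_{peer})\,p_{parent}$ modulates
  initiation, progression and experimenter relapse through the
  constant-elasticity multiplier $(SP/SP_{ref})^{s_{social}}$. As youth
  smoking rises, pressure rises, and initiation rises further.
* **Secondhand smoke and nicotine dependence (reinforcing).** The same
  exposure index primes dependence among non-smokers through the linear gain
  $1 + s_{shs}\,SHS$ on initiation. We reuse one index for both loops rather
  than introducing a separate exposure submodel: it keeps the boundary
  minimal and the two loops share their driver in any case.
* **Smoking quantity and price (reinforcing via dependence).** Monthly
  quantity is smoking frequency times cigarettes per day. The
  income-adjusted price $(retail + tax)/income$ moves quantity with
  elasticity $\varepsilon_q \le 0$; relative quantity moves initiation and
  progression ($s_{q,init}, s_{q,prog}$), attenuates cessation and fuels
  relapse (dependence elasticity $s_{nd}$), while price separately raises
  cessation ($\varepsilon_{cess} \ge 0$). Expressing price relative to
  average income proved necessary for a sensible historical trajectory: the
  nominal price trend alone overstates the economic burden late in the
  window.
* **Risk perception (balancing).** Perceived risk is proxied by a
  first-order exponential smoothing of averaged prevalence (delay
  $\tau_{risk}$), itself a stock. Smoothed prevalence above its 1992 anchor
  suppresses initiation through
  $1/(1 + s_{risk}\,\max(0, \hat p/\hat p_{ref} - 1) + s_{fund,risk}\,\max(0, F/F_{ref}-1))$.
  The deviation is one-sided by design: the loop counteracts increases in
  smoking, but a decline below the historical anchor does not *reward*
  initiation. A two-sided form would also reverse the sign of the
  risk-gain polarity at low prevalence, which contradicts the loop's
  intended direction.
* **Marketing (step + funding channel).** Tobacco marketing multiplies the
  social-pressure channel of initiation. The 1998 Master Settlement
  Agreement marketing restrictions enter as a left-closed step reduction by
  the fraction `m_msa`; programme funding above its reference further lowers
  the index with gain `s_fund`.

All functional forms are the package's own choices: the field's convention
for such models is multiplicative hazard modifiers with constant-elasticity
(power) forms for continuous drivers and linear gains for bounded indices,
normalised at documented reference conditions so that calibration is
identifiable and switched-off loops reduce to a linear chain.

## Numerical engine

Stocks are integrated with explicit Euler on a fixed grid (default 1/8 year,
1992–2032). Per step the engine evaluates auxiliaries (all multipliers are
recorded), then flow rates, then the state update. Euler with a small step
was preferred over a higher-order scheme because it is the transparent,
auditable baseline for this model family; the test suite verifies
first-order convergence against closed forms (exponential decay,
matrix-exponential linear chains) and that halving the step changes the 2032
endpoint by under 0.5%. A stock driven negative within a step raises an
error rather than being clamped — all outflows are hazard × stock, so
negativity indicates a malformed equation or an over-large step, not a
meaningful state. Yearly exogenous series are interpolated linearly and
extrapolated as constants; policy steps are applied as exact step overrides
(not interpolated), so scenario runs are bit-identical to the base run
before the policy year.

## Synthetic study inputs

The pipeline is exercised end-to-end on synthetic data, so nothing needs to
be downloaded:

* `generate_target_series()` produces the historical-shaped prevalence
  target: a logistic rise toward a peak multiplied by an exponential decline
  after it, with optional truncated Gaussian (or binomial) observation
  noise. Defaults — 16% in 1992, 22% peak in 1997, 4.5%/yr decline — are
  **illustrative stand-ins** that mirror the qualitative national trend
  (rise, mid-90s peak, monotone decline); they are not survey values, and
  passing tests on them demonstrates the machinery, not agreement with any
  published series.
* `generate_env_inputs()` produces the exogenous series: pre-tax price
  $1.56/pack growing 2.5%/yr, an income index growing 2%/yr, a constant
  $0.44/pack excise tax, 8000 entrants/yr, parental prevalence declining
  linearly from 25%, constant $9.80 per-capita programme funding, and
  retailer compliance 0.73/0.78 (middle/high). The compliance assignment
  follows the survey-report reading that gives high school the higher
  compliance; the reverse assignment can be passed explicitly to
  `env_inputs()`.

What the generator does *not* emulate: survey weighting and design effects,
cohort-specific reporting differences, serially correlated measurement
error, and migration. Results on synthetic data therefore say nothing about
the true effect sizes in any real population — they validate structure,
calibration behaviour and policy logic.

## Calibration

`calibrate()` is the package's central fitting function: bounded
least-squares on the sum of squared prevalence errors (unweighted, on the
averaged series by default; per-cohort records are supported), minimised by
Levenberg–Marquardt from multiple seeded random starts plus a warm start at
the incoming parameter values. It returns a classed `smoking_fit` object
with the usual `coef`/`residuals`/`predict`/`plot`/`simulate` methods.

Not everything is identifiable from one noisy prevalence series, and the
defaults reflect a deliberate two-stage design:

1. The soft loop strengths and elasticities (`s_social`, `s_shs`,
   elasticities, funding and availability gains) are fixed design constants,
   set once so the model family behaves sensibly (see below).
2. The well-identified quantities — the initiation hazard `h_init`, the
   marketing step `m_msa`, the risk gain `s_risk` — are fitted to the
   target. The package defaults *are* the result of this calibration
   against the default synthetic target (RMSE ≈ 0.007 in prevalence units,
   peak year 1998 vs 1997 requested).

Under the synthetic environment, the income-adjusted price is nearly flat
over 1992–2014 (price growth 2.5%/yr vs income growth 2%/yr), so the price
elasticities are structurally unidentifiable from the historical window —
they matter only when a policy moves price sharply. They are therefore
design constants, not fitted quantities. The parameter-recovery study in the
test suite makes the converse point explicit: with five free parameters
(`h_init`, `s_social`, `m_msa`, `h_quit_exp`, `h_prog`), recovery to within
15% under observation noise of 0.005 requires per-cohort observation series
over the full simulated horizon; a single 23-point averaged series supports
only about four effective degrees of freedom.

## Policy experiments

`scenario_catalog()` defines the base case and five policy runs, all
starting in 2015 as step changes: excise tax from $0.44 to $1.44 or $2.20
per pack (full pass-through to the consumer price), programme funding from
$9.80 to $20 per capita (split between the marketing and risk-perception
channels with equal design weight), retailer compliance to 95% in both
cohorts (entering only through perceived availability), and all three
together with the higher tax. Outcomes are percent reductions in the
averaged 2032 prevalence relative to base, reported to one decimal.

Under the default calibration the levers rank tax ($2.20) > tax ($1.44) >
programme funding > retailer compliance, all strictly positive, and the
combined run is additive within two percentage points of the sum of its
components. Two design notes on magnitudes:

* The absolute reductions (≈ 22/14/4/2% and 26% combined) are deliberately
  moderate. In this functional-form family the three levers multiply the
  same behavioural flows, so their combined effect falls short of the sum by
  roughly the pairwise products of the individual effects; with a ~30% tax
  effect that shortfall alone exceeds three percentage points, and every
  loop-gain configuration we explored widened rather than closed it.
  Requiring near-additivity therefore bounds how large the individual
  effects can be. The *ordering* of the levers — the robust, transferable
  finding in this literature — is preserved at any scale.
* Tax works through both consumption (lower quantity → lower initiation and
  progression, weaker dependence) and cessation; the calibration weights the
  cessation channel more heavily, which also reduces the overlap between
  levers and keeps the combined effect near-additive.

## Sensitivity analysis

`sensitivity_sweep()` re-runs the base simulation one parameter at a time
and separates *level* change (percent change in 2032 prevalence) from
*behaviour-mode* change. The mode criterion is operationalised as: peak year
shifted by at most two years, and the sign pattern of yearly differences
unchanged after 3-point median smoothing, with a deadband of $10^{-4}$
(changes far below survey measurement noise do not count as a sign), and
excluding the first post-initialisation year, whose sign reflects the
imposed 1992 stock decomposition rather than the dynamics.

`default_sweep()` uses two tiers of plausible ranges: ±10% for the base
hazards (pinned down by the historical fit) and ±30% for the soft strengths
and elasticities (estimated from qualitative information, hence the wider
uncertainty). On the default calibration every swept parameter preserves the
behaviour mode, and the social-pressure elasticity produces the largest
level change — the model's conclusions are most contingent on the
hardest-to-measure input, which is exactly what the sweep is meant to
surface.

## Degenerate inputs and numerical conventions

* Availability is floored at 0.01 so the power form stays finite as
  compliance approaches 1.
* The risk-multiplier denominator is used as-is; with the one-sided
  deviation it cannot fall below 1.
* Ties in the peak-year search resolve to the earliest year; series shorter
  than three points are rejected.
* Collapsed calibration bounds (lower = upper) skip the optimiser and return
  the point with its loss.
* Entry feeds never-smokers only (entrants are ~11-year-olds); cohort
  mortality is ignored over this age range and horizon.
* The initial 1992 stocks match the target prevalence with a 70/30
  experimenter/smoker split among current users and a 10% past-user pool
  split 50/50 — all four fractions are arguments of `initial_stocks()`,
  since the decomposition is unobserved.

## Problem sizes used by the shipped studies

The test suite and the acceptance script run the full pipeline at dt = 1/8
year for simulations (321 grid points over 1992–2032) and dt = 1/4 year
inside optimisation loops, with 100 random parameterisations in the
conservation battery, 6–8 optimiser starts in calibration studies, and
five-point sweeps over sixteen parameters in the sensitivity battery. These
sizes were chosen to characterise the estimator and engine well while
keeping a full run in the minutes range on a laptop.

## Known limitations

* Effect magnitudes are calibrated to a synthetic target and are not
  estimates for any real population; only structural conclusions (ordering,
  direction, near-additivity) transfer.
* Other tobacco products and e-cigarettes are out of scope (the
  corresponding multiplier is fixed at 1), as are demographic covariates,
  migration and mortality.
* Parental smoking is exogenous by default; the generational closure of the
  social-pressure loop (today's adolescents becoming tomorrow's parents)
  barely acts within a 40-year window and is omitted.
* The model is deterministic; parameter uncertainty is explored by sweeps,
  not by stochastic simulation or Bayesian posterior inference.

## A minimal session

```{r example, eval = FALSE}
env <- generate_env_inputs()
target <- generate_target_series()

fit <- calibrate(target, env,
                 free = list(h_init = c(0.03, 0.35), m_msa = c(0.05, 0.7),
                             s_risk = c(0.02, 2)),
                 n_starts = 6)
print(fit)

outcomes <- run_policy_comparison(fit$params, env)
report_policy_table(outcomes)
plot(outcomes)

sens <- sensitivity_sweep(fit$params, default_sweep(fit$params), env)
print(sens)
```
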