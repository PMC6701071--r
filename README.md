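# smokedyn

System-dynamics simulation of adolescent smoking and tobacco-control
policies.

## What this is for

Evaluating anti-smoking policies from observational data is hard:
appropriate control groups are rare, and conventional regression imposes a
one-way relationship on quantities — smoking behaviour and nicotine
dependence, prevalence and social pressure — that actually feed back on each
other. `smokedyn` takes the simulation route: a compartmental stock-and-flow
model of youth smoking whose feedback loops are explicit, calibrated to a
historical prevalence series, validated by sensitivity analysis, and then
used to run policy experiments that are impossible observationally (change
one lever, hold everything else fixed).

It is aimed at tobacco-control researchers and modellers who want a tested,
reusable, scriptable implementation of this model family — not a black box:
every multiplier the model computes is recorded in the trajectory.

## The model in brief

Two school cohorts (middle, ages 11–14; high, ages 15–18) form an aging
chain. Each cohort holds five mutually exclusive stocks — never-smokers,
current/former experimenters (< 100 lifetime cigarettes), current/ex smokers
(≥ 100) — linked by initiation, progression, cessation and relapse flows,
with graduation at 1/(4 yr) between cohorts. Writing $p$ for past-30-day
prevalence, each flow is a base hazard times reference-normalised
multipliers:

* social pressure (reinforcing): $(SP/SP_{ref})^{s_{social}}$ with
  $SP = w\,p_{peer} + (1-w)\,p_{parent}$;
* secondhand-smoke-primed dependence (reinforcing): $1 + s_{shs}\,SP$;
* price via smoking quantity: $Q = Q_{ref}(P/P_{ref})^{\varepsilon_q}$
  moving initiation/progression, attenuating cessation and fuelling relapse
  through $(Q/Q_{ref})^{\pm s_{nd}}$, with price separately raising
  cessation as $(P/P_{ref})^{\varepsilon_{cess}}$, where
  $P = (retail + tax)/income$;
* perceived availability: $(A/A_{ref})^{s_{avail}}$, $A = 1 - compliance$;
* risk perception (balancing): initiation suppressed by smoothed prevalence
  above its 1992 anchor; and
* a marketing index stepped down by the 1998 marketing restrictions and by
  programme funding.

Integration is explicit Euler on a fixed grid (default dt = 1/8 yr,
1992–2032), convergence-tested against closed forms. Policy levers — excise
tax, comprehensive-programme funding per capita, retailer compliance — enter
as step changes in 2015 and are scored by the percent reduction in averaged
2032 prevalence relative to the base run.

## Worked example

```r
library(smokedyn)

env    <- generate_env_inputs()       # synthetic exogenous series
target <- generate_target_series()    # synthetic historical prevalence

fit <- calibrate(target, env,
                 free = list(h_init = c(0.03, 0.35), m_msa = c(0.05, 0.7),
                             s_risk = c(0.02, 2)),
                 n_starts = 6)
print(fit)
#> Calibrated youth smoking model
#>
#> Fitted parameters:
#> h_init  m_msa s_risk
#> 0.1321 0.4041 0.1526
#>
#> SSE 0.00118, RMSE 0.0072 (prevalence units) over 23 observations
#> Simulated peak year: 1998

outcomes <- run_policy_comparison(fit$params, env)
report_policy_table(outcomes)
#> Policy comparison (prevalence at 2032, percent reduction vs base)
#>       scenario prevalence_2032 base_prevalence_2032 pct_reduction
#>   ALL_COMBINED          0.0470               0.0633          25.7
#>        TAX_220          0.0497               0.0633          21.5
#>        TAX_144          0.0544               0.0633          14.1
#>     FUNDING_20          0.0607               0.0633           4.1
#>  COMPLIANCE_95          0.0622               0.0633           1.8
```

Reading the numbers: the calibrated model tracks the synthetic target to
within 0.7 prevalence points (RMSE) and peaks within a year of the requested
peak. In the policy runs, the $2.20 excise tax is by far the strongest
lever (21.5% lower 2032 prevalence than the no-policy base case of 6.3%),
funding and retailer compliance are an order of magnitude weaker, and the
three policies together (25.7%) are close to the sum of their separate
effects — the levers act nearly additively. The ordering of the levers, not
the absolute percentages (which are calibrated to synthetic data), is the
transferable result.

The methods vignette (`vignettes/youth-smoking-model.Rmd`) documents the
model equations, the calibration design, what the synthetic generator does
and does not emulate, and known limitations. A thin command-line front end
is installed at `inst/scripts/smokedyn` with subcommands `synth`,
`simulate`, `calibrate`, `sensitivity` and `policy-compare`.

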