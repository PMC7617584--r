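# distressim

A dynamic, stochastic, discrete-time microsimulation of the UK working-age
population for asking a health-in-all-policies question: **how much
psychological distress did the UK's tax and social-security response to the
COVID-19 economic crisis prevent?**

The package is written for quantitative social scientists and public-health
modellers who want a self-contained, desk-scale implementation of the full
pipeline: a synthetic household-structured population stands in for
restricted-access survey microdata; a parametric tax-benefit calculator stands
in for a full static microsimulation model; everything else — the
discrete-choice labour-supply model, the reduced-form pandemic transitions,
the two-step distress process, the paired-run bootstrap — is implemented in
full.

## The model in brief

Each simulated year, every agent passes through:

1. **Alignment** of (sex × age band × region) cells to external population
   targets.
2. **Demographic/education/health processes** (ageing, mortality, retirement
   at 65, education completion, self-rated-health walk, long-term-sickness
   hazards).
3. **Labour supply.** In normal years, each benefit unit chooses weekly hours
   `h ∈ {0, 10, 20, 30, 40}` per at-risk adult (up to 25 alternatives for a
   couple) to maximise a random utility
   `U_j = β_y · y_j / 1000 + Σ_a h_aj · β_h(a) + γ · 1[status kept] + ε_j`,
   with `y_j` the unit's disposable income in alternative `j` and
   `ε_j ~ Gumbel(0, λ)`.  In the pandemic years 2020–21, hours come instead
   from multinomial-logit transitions between employment states
   (employed, not employed, full/partial furlough); in the counterfactual
   the furlough states do not exist and their probability mass moves to
   non-employment.
4. **Tax-benefit interaction.** Banded income tax, flat NI, and a Universal
   Credit award `max(0, 52·(allowance + uplift + child elements) − 0.63 ·
   net earnings)`; furlough pay is `min(0.8 · usual wage, £2,500/month)`.
   Incomes are equivalised (modified OECD) and poverty is income below 60%
   of the 2019 median, fixed thereafter.
5. **Psychological distress (GHQ-12).** Step 1 predicts a baseline Likert
   score (0–36) and caseness log-odds from lagged distress, excluding
   current-period economics.  Step 2 adds the configured effects of economic
   transitions — e.g. +2.74 Likert points for a male employment exit, +1.46
   on the caseness log-odds — plus non-economic pandemic constants in
   2020–21.

Two policy scenarios are contrasted: the **observed** crisis response
(£20/week Universal Credit uplift + furlough scheme) and a **counterfactual**
that keeps pre-crisis 2019 policies throughout.  Paired runs share one
bootstrap draw of all regression coefficients and common random numbers
keyed by (person, year, process), so arm differences isolate the policy
effect.  Across runs, outcomes are reported as the 25th/500th/975th ranked
values (at 1000 runs; the ceiling-rank generalisation otherwise).

## Worked example

```r
library(distressim)

pc  <- population_config(n_individuals = 20000, seed = 1)
pop <- generate_population(pc)
print(pop)
#> Synthetic population: 20000 persons (11610 benefit units), scaling factor 3345
#>   working age 25-64: 10269; employment 75.0%, CMD prevalence 20.3%, median Likert 11.2

cfg <- scenario_config(population = pc, seed = 7)
pr  <- run_paired(cfg)   # observed vs counterfactual, common random numbers
print(pr)
#> Paired scenario run (observed vs counterfactual), draw 0
#>  year employment_rate poverty_rate cmd_prevalence
#>  2017          0.0000       0.0000         0.0000
#>  2018          0.0000       0.0000         0.0000
#>  2019          0.0000       0.0000         0.0000
#>  2020          0.1238      -0.1243        -0.0333
#>  2021          0.1440      -0.1512        -0.0078
#>  2022          0.0220      -0.0179         0.0163
#>  2023          0.0057      -0.0040         0.0069
#>  2024          0.0007      -0.0008         0.0052
#>  2025          0.0002      -0.0002         0.0033
```

Reading the table: the rows are yearly differences (observed −
counterfactual).  Pre-2020 the arms share policy systems and random numbers,
so every difference is exactly zero.  In 2020 the policy response holds the
employment rate 12.4 percentage points higher, and prevents a 3.3-point rise
in the prevalence of common mental disorders (CMDs, negative = preventative);
in 2022 the sign flips briefly as the counterfactual labour market rebounds,
then the arms reconverge.

Converting the 2020 distress effect to national head counts and value:

```r
eff20 <- paired_effect(pr$observed, pr$counterfactual, "cmd_prevalence", 2020)
cases <- headcount(eff20, pr$observed$aggregates$n_working_age[4],
                   pc$scaling_factor)
cases
#> [1] 1164000
qaly_valuation(cases)$value / 1e9   # billions GBP at 0.13 QALY x 70,000 GBP
#> [1] 10.59
```

For uncertainty intervals, `run_experiment(cfg, n_runs = 100)` repeats the
paired design with bootstrapped coefficients and `summary()` /
`subgroup_table()` produce the ranked-interval tables;
`plot(experiment)` draws the paired-difference histogram.

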