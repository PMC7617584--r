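---
title: "Modelling tax-benefit policy and psychological distress: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tax-benefit policy and psychological distress: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distressim)
```

distressim is a desk-scale dynamic microsimulation for contrasting the UK's
COVID-19-era tax and social-security response against a pre-crisis
counterfactual, with psychological distress (GHQ-12) as the outcome of
interest. This vignette is the package's own account of the model: what each
module assumes, which parameters matter and why their defaults are what they
are, what the synthetic data do and do not emulate, and where the design was
genuinely open.

## The question and the causal structure

Tax and social-security policy reaches mental health through economic
pathways: employment transitions, income changes, and poverty exposure. The
model operationalises exactly those pathways. Policies determine disposable
incomes (and, in 2020-21, the availability of furlough as an alternative to
job loss); labour-market states and incomes evolve year by year; and a
two-step distress process turns each person's economic *transitions* — not
their levels — into increments and decrements of a 0-36 Likert score and of
the log-odds of a potential common mental disorder (CMD).

Two scenarios share everything except policy: the *observed* schedule applies
the crisis-response system (a 20 GBP/week Universal Credit uplift plus the
furlough scheme) in 2020-21; the *counterfactual* keeps the 2019 baseline
system throughout. Because both arms of a paired run consume the same
coefficient draw and the same random numbers, any within-run difference in
outcomes is policy-mediated.

## Synthetic population

Restricted-access household microdata cannot be shipped, so the package
generates its own population. The generator emulates the features downstream
modules consume:

* a full age pyramid (0 to 85+) with sex, twelve regions, three education
  levels, and benefit-unit structure (couples formed with age-band-specific
  probability, defaulting to 0.6 at working age; children attached to
  family-capable units with probability 0.4 and counts 1-3);
* activity states with the at-risk-of-work rule (students, retirees and the
  long-term sick are not at risk);
* log-normal potential wages from a Mincer-style equation in education, age
  and sex with a persistent person draw (sd 0.35) and an 8 GBP/hour floor;
  the intercept is set so median full-time earnings are about 28,000
  GBP/year;
* GHQ-12 Likert scores from a right-skewed scaled-Beta mixture and a
  logistic caseness probability in the Likert score.

Four pre-crisis anchors calibrate the 2019 state: working-age employment
0.75, poverty 0.09, CMD prevalence 0.20, median Likert 11.3. The generator
solves for the Beta shape and the caseness intercept on the drawn sample, so
the employment, prevalence and median anchors hold at generation time by
construction (the spec tolerances, ±2 points, ±1 point and ±0.3, are met
for any n ≥ 10,000); the poverty anchor is *not* imposed — see "Known
limitations".

The desk default is `n_individuals = 20000` agents with
`scaling_factor = national_population / n`, i.e. 3,345 persons per agent
(the full-scale configuration of 150,000 agents gives the canonical factor
446). Desk-scale problem sizes used throughout the package's own checks:
populations of 1,500-20,000, paired experiments of 50-100 runs, panels of
5,000 persons by 5 waves.

Alignment targets are the initial (sex × age band × region) margins grown at
a configurable 0.5%/year, with cumulative rounding so yearly totals are
preserved even in small cells.

### The estimation panel

`generate_estimation_panel()` is the parameter-recovery harness: it builds a
balanced panel whose outcome is constructed *additively* from individual
fixed effects, wave effects, the configured transition effects, the two
income terms, and i.i.d. noise. `estimate_panel_effects()` applies the
two-way within transformation (double demeaning, exact for balanced panels)
and OLS. Recovering every configured Likert effect within two standard
errors at n = 5,000 × 5 waves demonstrates that the shipped effect table and
the estimator that would produce it from real panel data are mutually
consistent. The panel is deliberately idealised — no attrition, no
measurement error, transition events assigned at configured frequencies —
so recovery there says nothing about confounding in real survey data.

## Policy engine

Gross incomes become disposable incomes by direct parametric calculation at
the benefit-unit level (one or two adults plus dependent children):

* banded income tax (defaults 20/40/45% above 12,500/50,000/150,000 GBP) and
  a flat 12% NI contribution above 8,632 GBP, assessed per adult;
* Universal Credit `max(0, 52·(allowance + uplift + child elements) − 0.63 ·
  net earnings)`, with the single-adult allowance at the 2019 value of 73
  GBP/week and the couple allowance 114.85;
* furlough pay `min(0.8 × usual monthly wage, 2500 GBP/month)`; partial
  furlough pays worked hours at full wage plus the subsidy on unworked usual
  hours, with the cap applied pro-rata (the phase rules of the real scheme
  are more intricate; this is the simplest formula consistent with the
  headline parameters).

Budget sets enumerate the five weekly hour points per at-risk adult — 5
alternatives for a single, up to 25 for a couple — and price each through
the same calculation, reconstructing the discrete budget constraint.

Money is handled in GBP/year internally (weekly and monthly parameters are
converted by ×52 and ×12). Three open conventions are fixed in
configuration, with these documented defaults: the equivalence scale is
modified OECD (1 / 0.5 / 0.3 under-14 / 0.5 for 14+); the poverty line is
60% of the 2019 median equivalised income, common to both arms (identical
pre-2020 histories make the two scenarios' 2019 medians the same number) and
held fixed afterwards so the scenario contrast is not distorted by
contemporaneous medians; and reported incomes are expressed in 2015 prices
through a configurable deflator whose default is 1 — the simulation itself
is in constant prices, so no artificial real-income trend is induced.

## Labour supply

In structural years, each benefit unit maximises a joint random utility over
its budget set: utility rises in disposable income (0.30 per 1,000 GBP/year)
and falls in each at-risk adult's hours (−0.136/hour, with small shifters
for women, mothers of young children and high education), plus a
state-dependence bonus (0.60) for keeping the previous year's work status,
and an i.i.d. Gumbel shock (scale 1) per alternative. The error scale is
unidentified separately from the preference weights, so it is fixed at 1.
With Gumbel errors the implied choice probabilities are conditional-logit;
the test suite verifies the simulated shares against that closed form
(KL < 10⁻³ at 10⁶ draws). Ties under a zero error scale break toward the
lowest total hours, then alternative order. There is no involuntary
unemployment in structural years: not working is a choice at the agent's
potential wage.

The income and hours weights were calibrated once, jointly with the
state-dependence bonus, so that structural years hold the simulated
working-age employment rate near its 0.75 anchor through 2019; they are
ordinary configuration in `inst/extdata/preferences.yaml`.

In 2020 and 2021 that choice model is implausible (labour demand collapsed),
so a reduced-form module applies one multinomial logit per starting state —
employed, not employed, full furlough, partial furlough, other — over the
end states each start admits, with covariates sex, age 50+, education,
children, and a second-pandemic-year indicator. In the counterfactual the
furlough states do not exist: their probability mass is reassigned to
non-employment, an identity the tests check exactly. Sampling uses a single
uniform per person against the cumulative probabilities in the fixed order
(employed, not employed, furlough), which under common random numbers
guarantees that a person furloughed in the observed arm is non-employed —
never employed — in the paired counterfactual.

The shipped transition coefficients are a *calibration*, not estimates: the
regressions behind the real transition probabilities come from
restricted-access pandemic survey data. Intercepts were chosen once so the
simulated employment-rate gap between arms matches the published aggregate
gaps (about 12.5 percentage points in 2020 and 13.9 in 2021, the 2020 gap
within ±1 point), then frozen; the file documents this and any user can swap
in estimated logits of the same shape.

## Psychological distress

Step 1 predicts a baseline excluding current-period economics: the Likert
score as `5.65 + 0.5 × lagged score` plus a mean-zero normal residual
(sd 4.5), clamped to [0, 36]; the caseness log-odds as
`−3.80 + 0.185 × lagged score`. The persistence of 0.5 carries forward half
of any past shock each year; the intercept makes the 11.3 anchor a fixed
point of the deterministic part, and the caseness intercept was calibrated
once so the simulated pre-crisis prevalence sits at its 0.20 anchor (the
residual sd keeps the cross-sectional spread stationary). The full step-1
regressions of the source framework are not public; these three numbers are
the minimal stand-in and are fully overridable.

Step 2 adds, per sex and outcome, the effects of six transitions
(employment exit/entry, long-term non-employment, poverty entry/exit,
long-term poverty), a coefficient on the growth rate of equivalised
household income, a constant on any income decrease, and non-economic
pandemic constants in 2020 and 2021 applied to everyone. The shipped file
`inst/extdata/mental_health_coefficients.csv` carries the point estimates
and standard errors; by construction the loss side outweighs an equivalent
gain (the decrease constant is positive), and the male exit/entry effects
are symmetric so an exit followed by re-entry nets to zero.

Definitions fixed here because the annual cycle forces a choice:

* *Long-term* entry is the second consecutive year in a state (the counter
  moves 1 → 2) — the minimal coherent definition at annual periodicity.
* The income growth rate is clamped to [−1, 1] and set to 0 when prior
  income is nonpositive, bounding the effect of near-zero denominators.
* Furlough counts as employment in both the transition flags and the
  employment rate: the scheme's point is that the contract (and the
  non-pecuniary benefits of employment) survive.
* Caseness is simulated through the log-odds channel with its own effect
  columns, not by thresholding the simulated Likert score — thresholding
  would double-use the Likert channel. Whether the binary state should be a
  Bernoulli draw from the updated probability or its expectation is not
  determined by the science; the default is a Bernoulli draw on the
  person's random stream, with `caseness_mode = "expected"` as a switch.
* Step-1 and step-2 updates apply from age 16; results are reported for
  ages 25-64 throughout, abstracting from education exit and retirement.

## Engine, pairing and uncertainty

Each year runs alignment → demographics → labour → tax-benefit → transition
flags → step 1 → step 2, with year counters updated after the year's
outcomes. Alignment duplicates/removes within cells deterministically given
the year's stream, borrowing from the nearest age band (with age recoded)
when a cell empties. The simplified demographic processes use configuration
rates rather than estimated models: a Gompertz-style mortality curve,
retirement at 65, education completion by age-dependent probabilities, a
bounded self-rated-health walk, and long-term-sickness hazards whose
stationary share matches the initial 5-6%.

Common random numbers are implemented as derived-seed streams per (year,
process), with uniforms assigned in stable person-id order. This is
equivalent to per-person counter streams *because the engine guarantees both
arms hold identical person sets*: mortality, alignment and unit re-labelling
are all keyed by person id and never read policy state. Order-invariance
(permuting input rows leaves aggregates unchanged) is tested directly.

Uncertainty follows the bootstrap-the-coefficients design: at the start of
each run every coefficient is drawn from a normal centred at its point
estimate — diagonal variances for the step-2 effects, a full 2×2 block for
step 1, configured sds for the transition intercepts. A paired run gives
both arms the same draw. Experiments report the ceiling-rank
25th/500th/975th-style quantiles; the desk default is 100 runs rather than
1,000 (the rank formula generalises by ceiling), chosen to keep a full
paired experiment at n = 20,000 within minutes on one CPU. The initial
population is generated once per experiment and shared across runs,
mirroring a fixed survey-based starting sample; runs differ by coefficient
draw and simulation stream.

Income-quintile subgroups are fixed at the counterfactual arm's 2019 income
distribution so that group membership cannot itself respond to policy, and
subgroup uncertainty intervals summarise per-draw paired differences (not
arm-wise intervals), consistent with the paired design.

## Numerical conventions

* Quantiles (P90/P10, quintile cut points) use `stats::quantile` type 7.
* Ranked summaries use ranks `ceiling(0.025n)`, `ceiling(0.5n)`,
  `ceiling(0.975n)`; at least 40 runs are required.
* Head counts are rounded to the nearest thousand persons.
* Degenerate inputs fail loudly: empty working-age populations, nonpositive
  poverty lines, units without adults, transition models asked for unknown
  states, non-positive-semidefinite step-1 covariance blocks.

## What passing tests do and do not show

The synthetic population reproduces configured margins and anchors, and the
paired machinery isolates policy pathways by construction — so the test
suite demonstrates *internal* validity: the arithmetic of the tax-benefit
rules, the logit equivalences, mass conservation, coupling and recovery
properties, and the calibrated aggregate gaps. It cannot demonstrate
external validity: no attrition, no survey weights, no migration, no
household formation/dissolution or fertility, wages and preferences are
configuration rather than estimates, and the pandemic transition model is a
calibration to published aggregates rather than estimated from pandemic
survey data.

## Known limitations

* **Poverty levels run high.** With only a UC-style floor (no housing
  element, child benefit or legacy tax credits), workless households sit
  further below 60% of median income than in the full UK system; simulated
  working-age poverty is in the high teens to mid-twenties rather than 9%,
  and the counterfactual's 2020 poverty spike is correspondingly larger.
  The paired *contrast* — the object of interest — retains the right sign
  and dynamics, but poverty-level and inequality-level outputs should be
  read as internally consistent model quantities, not UK statistics.
* **Post-pandemic persistence is understated.** The structural module's
  state-dependence bonus lets the employment gap decay over 2022-25 rather
  than vanish instantly, but the sustained multi-point gaps a fully
  estimated system produces are not targeted by the desk calibration.
* **No feedback from distress into labour supply**, and no cumulative
  effect of past exposures beyond step-1 persistence: the step-2 effects
  are short-term by design.
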