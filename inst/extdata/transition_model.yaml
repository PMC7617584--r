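# Reduced-form labour-market transition model for the pandemic years
# (2020, 2021). One multinomial logit per starting state; coefficients are
# log-odds relative to remaining in the starting state (for "other", relative
# to not_employed). Covariates: female, age50 (aged 50+), edu_low, edu_high,
# children (dependent children in the unit), year2021 (indicator for the
# second pandemic year).
#
# These defaults are a calibration: intercepts were chosen once so that the
# simulated employment-rate gap between the observed and counterfactual
# scenarios matches the printed aggregate gaps (about 12.5 percentage points
# in 2020, 13.9 in 2021); they are fully swappable via this file.
intercept_se: 0.04
states:
  employed:
    base: employed
    ends:
      not_employed:     {intercept: -2.62, female: 0.10, age50: 0.25, edu_low: 0.40, edu_high: -0.30, year2021: -0.29}
      furlough_full:    {intercept: -1.90, female: 0.15, edu_low: 0.30, edu_high: -0.40, children: 0.05, year2021: -0.85}
      furlough_partial: {intercept: -2.62, female: 0.15, edu_low: 0.20, edu_high: -0.30, year2021: -0.39}
  not_employed:
    base: not_employed
    ends:
      employed:         {intercept: -1.74, edu_high: 0.30, edu_low: -0.20, age50: -0.25, year2021: -0.22}
  furlough_full:
    base: furlough_full
    ends:
      employed:         {intercept: 0.47, edu_high: 0.20}
      furlough_partial: {intercept: -0.51}
      not_employed:     {intercept: -0.22, edu_low: 0.20, age50: 0.15}
  furlough_partial:
    base: furlough_partial
    ends:
      employed:         {intercept: 0.92, edu_high: 0.20}
      furlough_full:    {intercept: -0.69}
      not_employed:     {intercept: 0.00, edu_low: 0.20, age50: 0.15}
  other:
    base: not_employed
    ends:
      employed:         {intercept: -1.10}
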