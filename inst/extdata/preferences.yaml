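# Labour-supply preference coefficients for the discrete-choice random-utility
# module. Utility is linear in unit disposable income (per 1000 GBP/year) and
# in each at-risk adult's weekly hours, with small demographic shifters on the
# hours disutility and a state-dependence bonus for remaining in the previous
# year's employment state. Defaults calibrated once so that structural years
# hold the working-age employment rate near its pre-crisis anchor.
income_weight: 0.30        # utility per 1000 GBP/year, > 0
hours_weight: -0.136       # utility per weekly hour, < 0
female_shift: -0.004       # added to hours_weight for women
children_shift: -0.012     # added to hours_weight for women with children < 14
edu_high_shift: 0.004      # added to hours_weight for high education
state_dependence: 0.60     # utility bonus for keeping previous work status
error_scale: 1.0           # Gumbel scale of the taste shock
intercept_se: 0.0          # bootstrap sd for income_weight/hours_weight
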