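# Pre-crisis tax/benefit system (2019 rules, simplified parametric form).
name: uk2019_baseline
tax_thresholds: [12500, 50000, 150000]
tax_rates: [0.20, 0.40, 0.45]
ni_rate: 0.12
ni_floor: 8632
uc_standard_allowance: 73        # GBP/week, single adult 25+
uc_standard_allowance_couple: 114.85
uc_uplift: 0
uc_child_element: 53.5
uc_taper: 0.63
furlough_exists: no
furlough_rate: 0.8
furlough_cap: 2500
state_pension: 8767
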