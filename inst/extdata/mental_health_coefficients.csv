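effect,male_likert,male_likert_se,female_likert,female_likert_se,male_caseness,male_caseness_se,female_caseness,female_caseness_se,description
emp_exit,2.74,0.18,1.67,0.14,1.46,0.10,0.76,0.07,transition from employment to non-employment while at risk of work
emp_entry,-2.74,0.19,-2.12,0.15,-1.26,0.12,-0.93,0.08,transition from non-employment (at risk of work) to employment
ne_longterm,-0.32,0.22,-0.73,0.14,-0.16,0.12,-0.43,0.08,entry into long-term non-employment (second consecutive year at risk of work)
pov_entry,0.29,0.10,0.29,0.09,0.03,0.08,0.16,0.06,transition from non-poverty to poverty
pov_exit,-0.33,0.15,-0.12,0.13,-0.10,0.11,0.01,0.08,transition from poverty to non-poverty
pov_longterm,0.07,0.16,0.07,0.14,0.04,0.11,0.02,0.09,entry into long-term poverty (second consecutive year)
income_growth,-0.01,0.04,-0.12,0.05,-0.05,0.03,-0.08,0.03,coefficient multiplying the growth rate of equivalised household income
income_decrease,0.10,0.04,0.07,0.04,0.06,0.03,0.01,0.03,constant applied on any decrease in equivalised household income
pandemic_2020,0.83,0.08,1.41,0.08,0.63,0.08,0.83,0.05,non-economic pandemic-exposure constant applied to everyone in 2020
pandemic_2021,0.50,0.08,0.37,0.08,0.08,0.08,-0.04,0.05,non-economic pandemic-exposure constant applied to everyone in 2021
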