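employment_rate: 0.75
income:
  female: 37847.0
  male: 54690.0
  unknown: 46268.0
discount_rate: 0.015
friction_months: 3.0
disability_employment_loss: 0.225
disability_income_loss: 0.315
disability_benefit: 11506.0
apply_disability_benefit: no
hosp_bands:
- age_min: 0.0
  age_max: 17.0
  cost: 1766.0
  los: 1.2
- age_min: 18.0
  age_max: 39.0
  cost: 2720.0
  los: 1.8
- age_min: 40.0
  age_max: 59.0
  cost: 3480.0
  los: 2.3
- age_min: 60.0
  age_max: 79.0
  cost: 4660.0
  los: 3.0
- age_min: 80.0
  age_max: .na.real
  cost: 5325.0
  los: 3.9
hosp_cost_unknown: 4205.0
los_unknown: 2.3
omic_unit_cost: 417.0
working_age:
- 19.0
- 64.0
unknown_age_working_fraction: 0.45
unknown_age_assumed: 52.0
period_years: 5.0
daily_divisor: 365.0
disability_decrement: multiplicative
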