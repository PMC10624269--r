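schema: palneed-scenario/1
reference_year: 2015
tables:
  conditions: conditions.csv
  countries: countries.csv
  symptom_coefficients: symptom_coefficients.csv
  opioid_supply: opioid_supply.csv
  equianalgesic: equianalgesic.csv
  encounter_coefficients: encounter_coefficients.csv
  staffing_norms: staffing_norms.csv
  level_allocation: level_allocation.csv
config:
  at_least_weighting: prevalence
  pain_daily_dose_mg: 67.5
  dyspnea_daily_dose_mg: 10.0
  requirement_population: all
  procedural_fraction: 0.0
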