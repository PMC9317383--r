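schema_version: "1.0"
country: Niger
year: 2018
note: >
  2018 country-year inputs. Population aggregates, incomes and unit costs are
  published values; the working-age and female marriageable populations are
  back-computed from the published cohort counts (see field note).
demography:
  total_population: 22442948
  population_at_risk: 16540452
  population_working_age: 4465782
  female_population_marriageable: 2315625
  life_expectancy_at_birth: 62.0
  note: >
    population_at_risk is persons aged 0-29. population_working_age (15-29)
    and female_population_marriageable (women 15-29 at risk) are
    back-computed so that floor(pop * 0.0064) reproduces the published
    cohort counts 28,581 and 14,820 (the source prints no Niger-specific
    values for these populations).
economy:
  mean_annual_income: 570
  currency_label: USD
epidemiology:
  incidence_rate: 0.0064
  care_fraction: 0.10
  untreated_mortality: 0.90
  mean_age_at_death: 6
  at_risk_age_range: [0, 29]
  working_age_range: [15, 29]
  marriageable_age_range: [15, 29]
cost_schedule:
  - id: treatment
    label: Costs of treatment
    category: direct
    count_base: treated
    eligibility: all
    unit_cost_usd: 345
    native_amount: 255000
    native_currency: FCFA
    note: mean cost 255,000 FCFA (2001) converted to USD at the 2001 rate
  - id: surgery
    label: Costs of surgery
    category: direct
    count_base: treated
    eligibility: absolute
    eligibility_value: 6372
    unit_cost_usd: 400
    native_amount: 393
    native_currency: CHF
  - id: accommodation
    label: Costs of accommodation
    category: direct
    count_base: treated
    eligibility: absolute
    eligibility_value: 6372
    unit_cost_usd: 765
    native_amount: 752
    native_currency: CHF
  - id: psychological
    label: Costs of psychological management
    category: direct
    count_base: treated
    eligibility: absolute
    eligibility_value: 6372
    unit_cost_usd: 65
    native_amount: 58
    native_currency: CHF
  - id: physiotherapy
    label: Costs of physiotherapy
    category: direct
    count_base: treated
    eligibility: absolute
    eligibility_value: 6372
    unit_cost_usd: 254
    native_amount: 64
    native_currency: CHF
    note: >
      the USD figure is canonical; the CHF amount is a provenance note only
      (its implied conversion factor is inconsistent with the other rows).
  - id: income_assistance
    label: Costs of assistance with income-generating activities
    category: direct
    count_base: treated
    eligibility: absolute
    eligibility_value: 6372
    unit_cost_usd: 245
    native_amount: 233
    native_currency: CHF
  - id: schooling
    label: Costs of schooling / vocational training
    category: direct
    count_base: treated
    eligibility: absolute
    eligibility_value: 2166
    unit_cost_usd: 175
    native_amount: 163
    native_currency: CHF
  - id: care_abroad
    label: Costs of care abroad
    category: direct
    count_base: treated
    eligibility: absolute
    eligibility_value: 185
    unit_cost_usd: 85000
    native_amount: 77850
    native_currency: CHF
    note: mean cost of transfer and care abroad, including all charges
  - id: lost_production
    label: Costs of loss of production
    category: indirect
    count_base: working_age
    eligibility: all
    unit_source: mean_annual_income
  - id: premature_death
    label: Costs related to premature death
    category: indirect
    count_base: deaths
    eligibility: all
    unit_source: income_times_yll
  - id: inability_to_marry
    label: Costs of inability to marry
    category: indirect
    count_base: female_marriageable
    eligibility: all
    unit_cost_usd: 1000
    note: mean dowry and related marriage expenses
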