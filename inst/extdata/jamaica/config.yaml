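model:
  horizon: 15
  base_year: 2008
population:
  table:
  - age_band: all
    sex: all
    count: 1330000.0
  growth_rate: 0.02535784
needs:
  table:
  - condition: hypertension
    age_band: all
    sex: all
    rate: 0.372393247269116
    items_per_person_per_year: 6.0
  - condition: diabetes
    age_band: all
    sex: all
    rate: 0.148957298907647
    items_per_person_per_year: 6.0
  - condition: arthritis
    age_band: all
    sex: all
    rate: 0.148957298907647
    items_per_person_per_year: 3.0
  - condition: heart_disease
    age_band: all
    sex: all
    rate: 0.074478649453823
    items_per_person_per_year: 6.0
  - condition: copd
    age_band: all
    sex: all
    rate: 0.059582919563059
    items_per_person_per_year: 5.0
  - condition: renal_disease
    age_band: all
    sex: all
    rate: 0.029791459781529
    items_per_person_per_year: 8.0
  - condition: depression
    age_band: all
    sex: all
    rate: 0.074478649453823
    items_per_person_per_year: 6.0
  - condition: anxiety
    age_band: all
    sex: all
    rate: 0.089374379344588
    items_per_person_per_year: 4.0
  - condition: psychosis
    age_band: all
    sex: all
    rate: 0.014895729890765
    items_per_person_per_year: 10.0
  - condition: cancer
    age_band: all
    sex: all
    rate: 0.013406156901688
    items_per_person_per_year: 8.0
  - condition: hiv_aids
    age_band: all
    sex: all
    rate: 0.022343594836147
    items_per_person_per_year: 9.0
  - condition: influenza
    age_band: all
    sex: all
    rate: 0.148957298907647
    items_per_person_per_year: 3.0
  - condition: dengue_fever
    age_band: all
    sex: all
    rate: 0.007447864945382
    items_per_person_per_year: 4.0
  - condition: malaria
    age_band: all
    sex: all
    rate: 0.001489572989076
    items_per_person_per_year: 4.0
  - condition: tuberculosis
    age_band: all
    sex: all
    rate: 0.001489572989076
    items_per_person_per_year: 5.0
  - condition: rheumatic_fever
    age_band: all
    sex: all
    rate: 0.001489572989076
    items_per_person_per_year: 4.0
training:
  seats_per_year: 85.0
  programme_length_years: 4
  attrition_rate: 0.18
  graduate_outmigration_rate: 0.9
supply:
  entry_mode: regional
  public_entry_fraction: 0.1
  in_migration_per_year: 0.0
  entrant_age: 23
  min_age: 23
  max_age: 75
  stock_total: 55.0
  stock_mean_age: 36.0
  exit_rate: 0.05
workforce:
  participation_rate: ~
  employed_headcount: 30.0
  activity_rate: 1.25
  fte_hours_per_week: 40.0
  activity_cap: 1.5
  productivity_growth_rate: 0.0
requirement:
  public_sector_share: 0.3
  productivity: 16800.0
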