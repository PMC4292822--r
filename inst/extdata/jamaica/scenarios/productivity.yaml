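name: productivity_plus_5%_per_year
overrides:
- path: workforce.productivity_growth_rate
  start_year: 0
  type: set
  value: 0.05
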