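name: seat_increase_100%
overrides:
- path: training.seats_per_year
  start_year: 0
  type: scale
  value: 2.0
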