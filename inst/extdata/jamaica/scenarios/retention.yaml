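name: retention_25%
overrides:
- path: supply.entry_mode
  start_year: 0
  type: set
  value: public_direct
- path: supply.public_entry_fraction
  start_year: 0
  type: set
  value: 0.25
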