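# Demo cohort: cold vs warm chamber at the deep isoflurane dose.
conditions:
  - ambient_temp: 20
    iso_conc: 1.4
    group_label: cold
  - ambient_temp: 32
    iso_conc: 1.4
    group_label: warm
n_per_group: 3
seed: 42
eeg_span_min: [-2, 6]
temp_span_min: [-30, 50]
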