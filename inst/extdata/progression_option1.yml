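n_inputs: 8
orders:
  concrete9_weight:
    units_internal: 1
    units_hidden: 0
    pattern: net1
  abstract10:
    units_internal: 1
    units_hidden: 0
    pattern: net1
  formal11:
    units_internal: 12
    units_hidden: 0
    pattern: net1
  systematic12:
    units_internal: 12
    units_hidden: 4
    pattern: net3
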