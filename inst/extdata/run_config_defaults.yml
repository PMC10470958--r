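seed: 1
generate:
  dialects:
  - A
  - B
  ohc:
    A:
    - concrete9_weight
    - concrete9_distance
    - abstract10
    - formal11
    B:
    - concrete9_weight
    - concrete9_distance
    - abstract10
    - formal11
    - systematic12
  class_counts:
    A:
      concrete9_weight: 400
      concrete9_distance: 400
      abstract10: 467
      formal11: 467
    B:
      concrete9_weight: all
      concrete9_distance: all
      abstract10: all
      formal11: all
      systematic12: 33
train:
  lr0: 0.01
  lr_up: 1.05
  lr_down: 0.7
  err_ratio_threshold: 1.04
  max_validation_failures: 10
  performance_goal: 0.001
  max_epochs: 1000
search:
  patterns: net1
  trials: 20
  max_units: 20
  heuristic_p: 7.0
  efficiency_exponent: 1.5
  early_stop: yes
transfer:
  options:
  - 1
  - 2
  - 3
  lr_scales:
  - 0.8
  - 0.7
  - 0.5
  - 0.0
  dialect: B
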