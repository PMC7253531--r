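# Demo configuration: a small synthetic population (119 neurons, 10-min
# recordings at 20 FPS) that runs the full pipeline in about half a minute.
# Class counts give 84% active neurons split 60/32/8% into low/intermediate/
# high-firing phenotypes.
seed: 42
simulate:
  n_per_class:
    low: 60
    intermediate: 32
    high: 8
    inactive: 19
  duration_s: 600
process:
  window_frames: 5
  block_s: 25
screen:
  n_labeled_per_class: 20
infer:
  threshold_pct: 0.8
  tau_s: 1.0
cluster:
  k: 8
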