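# Demo experiment profile: a reduced cohort, few bootstrap replicates and
# few training epochs so the full grid finishes in minutes on one CPU.
# The full-scale protocol uses n_replicates: 200 and max_epochs: 250.
cohort:
  n_subjects: 400
  seed: 7
models:
  - name: saps_score
    type: saps_score
  - name: coxph_saps
    type: coxph
    features: [saps]
  - name: deepsurv_saps
    type: deepsurv
    features: [saps]
    fusion:
      max_epochs: 15
      patience: 5
      learning_rate: 0.002
  - name: deepsurv_multimodal
    type: deepsurv
    features: [saps, text, image]
    fusion:
      max_epochs: 15
      patience: 5
      learning_rate: 0.002
evaluation:
  n_replicates: 5
  seed: 1
outputs: results/demo
subgroups: true
hr_table: true
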