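# Demo pipeline configuration: a small synthetic cohort analysed end to end.
generator:
  n_participants: 600
  seed: 2024
cutoff: 8
estimation:
  n_folds: 10
  lambda_rule: min
  n_lambda: 50
nct:
  n_permutations: 200
  paired: true
resampling:
  n_boot: 200
  n_boot_ci: 200
  drop_proportions: [0.1, 0.3, 0.5, 0.7]
out_dir: clpnet-demo
seed: 11
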