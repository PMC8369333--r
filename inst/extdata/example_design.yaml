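# Example simulation design for `bayesequiv simulate`.
# Omitted fields keep the package defaults (see ?simulation_design).
settings:
  - "null"
  - "small"
n_grid: [50, 100, 150]
prior_scales: [1.0]
regions:
  - lower: -0.05
    upper: 0.05
  - lower: -0.1
    upper: 0.1
methods: [noh_bf, rope_hpd95, rope_support]
reps: 200
master_seed: 1
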