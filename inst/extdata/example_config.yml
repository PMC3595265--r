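# Example run configuration: a two-isolate pilot with moderate exchange rates
design:
  isolates: [CMW13582, CMW17568]
  n_transfers: 5
  clones_per_obs: 60
  baseline_freq: 0.5
params:
  crossover_rate: 0.1
  reciprocal_fraction: 0.5
  conversion_rate: 0.0
  divisions_per_transfer: 20
  array_size: 125
alpha: 0.01
df_convention: study
seed: 2024
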