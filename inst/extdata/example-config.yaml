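# Example experiment configuration for aedetect::run_experiment().
# Any key omitted falls back to default_experiment_config(); unknown keys
# are rejected. This smoke-scale setup finishes in about a minute.
seed: 1
output_dir: aedetect-smoke
data:
  n_train: 20
  n_val: 5
  n_test: 5
  height: 32
  width: 32
  lesion_area_min_px: 20
  lesion_area_max_px: 60
train:
  epochs: 3
evaluate:
  thresholds: [0.1, 0.2, 0.3]
  size_bins: 2
io:
  write_checkpoints: false
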