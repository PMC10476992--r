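# Default linacsched run configuration.
# Reproduces the documented default: a 1665-record cohort split 1165/500,
# depth-2 feature synthesis, 5-fold model selection (MAE loss), the
# 30-105 s accuracy grid, and a 10-h day of 1-h blocks with a 20-min
# daily QA reservation.
seed: 1
output_dir: "linacsched-output"
cohort:
  n_patients: 1665
  first_fraction_rate: 0.04
split:
  n_train: 1165
dfs:
  primitives: [count, sum, mean, min, max, std, identity, zscore]
  max_depth: 2
model:
  candidates: [linear, ridge, tree, forest]
  k_folds: 5
  loss: mae
  budget: 50
predict:
  floor_s: 120
evaluate:
  thresholds: [30, 45, 60, 75, 90, 105]
schedule:
  open: "08:00"
  close: "18:00"
  slot_l_length: 60
  daily_qa_minutes: 20
  state_thresholds: [20, 10, 5]
  section_length: 60
  slots_per_section: 4
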