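# Demonstration run configuration: a small synthetic cohort (2 subjects per
# group, 3 trials each, 6 s at 128 Hz) that exercises the full
# simulate -> features -> compare pipeline in a few seconds.
seed: 42
out_dir: ipvi_demo_out
cohort:
  groups:
    younger:
      n_subjects: 2
      hip_mult: {mean: 1.5, gsd: 1.4}
      noise_sd: {mean: 0.40, sd: 0.05}
    older:
      n_subjects: 2
      hip_mult: {mean: 20, gsd: 1.4}
      noise_sd: {mean: 0.55, sd: 0.06}
  trials_per_subject: 3
  duration_s: 6
  fs: 128
filter:
  order: 6
  cutoff_hz: 5
features:
  window_s: 1
  min_gap_s: 0.02
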