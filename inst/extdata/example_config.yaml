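seed: 1
phantom:
  grid_shape:
  - 32
  - 32
  - 32
cohort:
  n_subjects: 10
  n_sessions: 2
  scans_per_session: 3
  sigma_b: 0.01
  sigma_w: 0.005
  voxel_noise_sd: 0.005
acquisition:
  echo_times:
  - 4.61
  - 9.22
  - 13.83
  - 18.44
  repetition_time: 27.0
  field_strength: 3.0
  b0_direction:
  - 0.0
  - 0.0
  - 1.0
  snr: 100.0
methods:
- name: tkd
  delta: 0.2
- name: tikhonov
  lambda: 0.05
metrics:
  k1: 0.01
  k2: 0.001
  dynamic_range: 1.0
  window_sigma: 1.5
stats:
  n_boot: 1000
  alpha: 0.05
  bonferroni: no
compress: yes
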