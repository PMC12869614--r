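# Built-in synthetic study scenarios. Ground-truth rates are given in
# reporting units (min^-1) and converted internally to s^-1. Frame intervals
# and durations emulate the dog (7.65 s) and pig (13.4 s) acquisitions over
# 60-minute sessions; noise_sigma is the additive Gaussian noise SD as a
# fraction of the baseline signal.
dog_eob:
  species: dog
  agent: Gd-EOB-DTPA
  frame_interval: 7.65
  duration: 3600
  n_baseline: 8
  tristan: {k1_per_min: 1.0, k2_per_min: 0.027}
  fa: 0.25
  hct: 0.40
  portal_dispersion_tau: 20
  spleen_tau: 30
  noise_sigma: 0.005
  seed: 1
dog_gadovist:
  species: dog
  agent: Gd-BT-DO3A
  frame_interval: 7.65
  duration: 3600
  n_baseline: 8
  tristan: {k1_per_min: 1.0e-6, k2_per_min: 0.01}
  fa: 0.25
  hct: 0.40
  portal_dispersion_tau: 20
  spleen_tau: 30
  noise_sigma: 0.005
  seed: 1
pig_eob:
  species: pig
  agent: Gd-EOB-DTPA
  frame_interval: 13.4
  duration: 3600
  n_baseline: 5
  tristan: {k1_per_min: 0.24, k2_per_min: 0.15}
  fa: 0.25
  hct: 0.40
  portal_dispersion_tau: 20
  spleen_tau: 30
  noise_sigma: 0.005
  seed: 1
pig_eob_nospleen:
  species: pig
  agent: Gd-EOB-DTPA
  frame_interval: 13.5
  duration: 3600
  n_baseline: 5
  tristan: {k1_per_min: 0.24, k2_per_min: 0.15}
  fa: 0.25
  hct: 0.40
  portal_dispersion_tau: 20
  spleen_tau: 30
  noise_sigma: 0.005
  spleen_in_fov: false
  seed: 1
pig_bopta:
  species: pig
  agent: Gd-BOPTA
  frame_interval: 13.4
  duration: 3600
  n_baseline: 5
  tristan: {k1_per_min: 0.21, k2_per_min: 0.05}
  fa: 0.25
  hct: 0.40
  portal_dispersion_tau: 20
  spleen_tau: 30
  noise_sigma: 0.005
  seed: 1
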