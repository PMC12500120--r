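# Small end-to-end demo: 8 regions, 4 subjects, 3 stimulation intensities.
out_dir: tusplast_demo
master_seed: 7
stages:
  synth: true
  commodels: true
  fit: false
  cohorts: true
  phiid: true
  contrast: true
  associate: true
  sweep: true
synth:
  n_regions: 8
  n_subjects: 4
  density: 0.6
hopf:
  duration: 400
  trim: 50
cohorts:
  alpha: -1.0
  target: 1
contrast:
  n_perm: 200
sweep:
  alpha_grid: [-1.0, 0.0, 1.0]
  n_perm: 200
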