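# Demonstration plan: receptor-mobility comparison across the three
# conditions, plus gating, mEPSC and FLIM stages at desk scale.
name: fig4-demo
seed: 42
spt:
  conditions: [control, shisa6, shisa6_dEVTV]
  n_cells: 6
  receptors_per_cell: 40
  n_frames: 150
  max_disp: 0.5
  max_gap: 2
  d_threshold: 0.005
ephys:
  schemes: [control, shisa6]
  dt: 1.0e-4
mepsc:
  genotypes: [WT, KO]
  duration: 60
  threshold_sd: 5
flim:
  conditions: [control, shisa6]
  size: 32
  intensity: 2000
  photon_noise: true
  instrument_phase: 0.3
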