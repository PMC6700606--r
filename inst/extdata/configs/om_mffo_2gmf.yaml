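# Evolutionary force-field optimization (MFFO) of the 2GMF elastic
# folder model, production settings, oxidizing conditions. The optimized
# force field is then evaluated with the hm_2gmf.yaml ensemble settings.
system:
  pdb: 2GMF.pdb
  chain: A
  bridges: [[88, 121], [54, 96]]
optimizer:
  n_test: 16
  tau_run: 3.5e3
  delta_k_sd: 2.5
  F0: 0.9
  w: 0.2
  alpha: 0.03
  m_cycle: 50
  N_K: 16
  N_win: 6
  N_low: 4
  k_rand_range: [30.0, 60.0]
  init_k_grid: [20.0, 40.0, 60.0, 80.0]
  cycles: 30
run:
  temperature: 0.1
  dt: 5.0e-4
  oxidizing: true
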