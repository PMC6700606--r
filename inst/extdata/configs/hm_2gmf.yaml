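# Homogeneous elastic folder model of 2GMF (chain A, 121 resolved
# residues), production ensemble. Requires the 2GMF PDB file (not
# shipped); fetch it from the PDB and point `pdb` at it.
system:
  pdb: 2GMF.pdb
  chain: A
  bridges: [[88, 121], [54, 96]]
model:
  type: efm
  k_bend: 36.5
  k1_tor: 38.5
run:
  temperature: 0.1
  dt: 5.0e-4
  tau_frict: 1.0
  tau_run: 1.5e4
  n_trajectories: 2048
  sample_every: 2000
  environments: [reducing, oxidizing]
analysis:
  bridge_threshold_factor: 1.5     # times sigma_b1 (= 1.992 sigma)
  reopen_threshold_factor: 2.0
  persistence: 10
topology:
  loop_residues: [88, 96, 105, 113, 121]
  tail_residues: [43, 48, 53]
  tail_split_index: 2
  switch_width: 0.2
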