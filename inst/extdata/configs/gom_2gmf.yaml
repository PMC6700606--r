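# Clementi-type Go model of 2GMF, production folding ensembles at the
# kinetically optimal temperature (T = 0.7) and above it (T = 1.1).
# Contacts: SMOG-style shadow-map file when available, else the Calpha
# distance cutoff fallback.
system:
  pdb: 2GMF.pdb
  chain: A
  bridges: [[88, 121], [54, 96]]
model:
  type: go
  contact_file: null          # falls back to cutoff 7.5 A, |i-j| >= 3
  k_bend: 40.0
  k1_tor: 1.0
  k3_tor: 0.5
  cys_E_factor: 10.0          # E_ij = 10 kB T in oxidizing conditions
run:
  temperatures: [0.7, 1.1]
  dt: 5.0e-4
  tau_frict: 1.0
  tau_run: 1.5e4
  n_trajectories: 2048
  sample_every: 2000
  environments: [reducing, oxidizing]
topology:
  # the soft Go dihedrals need a denser reduction than the EFM
  loop_residues: [88, 92, 96, 101, 105, 109, 113, 117, 121]
  tail_residues: [43, 45, 48, 51, 53]
  tail_split_index: 3
  switch_width: 0.2
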