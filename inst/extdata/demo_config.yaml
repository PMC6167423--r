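# Demo: synthetic two-compound exposure study analysed against a toy network.
synth:
  shift_table: combined      # packaged table; flag columns define the groups
  n_control: 17
  n_dose: 12
  n_bins: 200
  noise_sd: 1.0
  confounder_sd: 12.0
  effect: 1.8
chemometrics:
  folds: 7
  n_perm: 50                 # demo-sized; the reference analysis uses 200
  vip_threshold: 1.5
  alpha: 0.05
  n_osc: 1
  max_A: 4
fingerprint:
  tol_ppm: 0.02
comparisons:
  - name: BPA_1e-6M_vs_control
    groups: [control, BPA_1e-6M, BPA_1e-9M, BPA_1e-12M]
  - name: E2_1e-9M_vs_control
    groups: [control, E2_1e-9M, E2_1e-12M, E2_1e-15M]
network:
  toy_n_metabolites: 30
  toy_n_reactions: 45
  toy_n_compartments: 2
  toy_hub_degree: 10
  weight_scheme: degree_squared
  pairs:
    - a: BPA_1e-6M_vs_control
      b: E2_1e-9M_vs_control
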