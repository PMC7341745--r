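# ideal peptide covalent geometry (Engh-Huber-style standard values)
bonds:
  n_ca: 1.458
  ca_c: 1.525
  c_n: 1.329
  c_o: 1.231
angles:
  n_ca_c: 111.2
  ca_c_n: 116.2
  c_n_ca: 121.7
  ca_c_o: 120.8
omega: 180.0
phi_psi:
  helix: [-57.0, -47.0]
  strand: [-139.0, 135.0]
  turn1: [-60.0, -30.0]
  turn2: [-90.0, 0.0]
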