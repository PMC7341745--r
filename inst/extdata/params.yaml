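# global force-field and solvation constants
eps_p: 4.0          # protein dielectric
eps_w: 80.0         # solvent dielectric
probe: 1.4          # solvent probe radius, Angstrom
k_coul: 332.0636    # electrostatic constant, kcal*A/mol/e^2
scale14_lj: 0.5     # 1-4 Lennard-Jones scale
scale14_coul: 0.8333333333333333  # 1-4 Coulomb scale (1/1.2)
hct_scale: 0.80     # HCT descreening radius scale
burial_scale: 0.80  # pairwise surface-burial scale
b_max: 50.0         # cap on effective Born radii, Angstrom
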