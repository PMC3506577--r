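charge_states:
- 2
- 3
n_spectra:
- 2000
- 2000
decoy_slope:
- 0.008
- 0.012
decoy_intercept:
- 20.0
- 25.0
mass_meanlog: 7.24422751560334977
mass_sdlog: 0.29999999999999999
mass_range:
- 600.0
- 4600.0
decoy_sd: 5.0
correct_fraction: 0.5
correct_offset: 25.0
correct_sd: 6.0
entrapment_fraction: 0.29999999999999999
il_twin_fraction: 0.05
mode: separate
n_true_proteins: 20
n_entrap_proteins: 50
seed: 42
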