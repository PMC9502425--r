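# PVPVA (Plasdone S-630): Carreau-Arrhenius refit of published rheometry,
# pycnometric and untapped-bulk densities.
name: PVPVA
eta0_Pa_s: 169.7
gammadot_c_per_s: 133.1
c: 0.387
Ea_J_per_mol: 198292
T_ref_K: 473
rho_bulk_kg_m3: 315
rho_true_kg_m3: 1190
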