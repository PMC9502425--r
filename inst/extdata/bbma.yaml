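# bBMA (Eudragit EPO, basic butylated methacrylate copolymer).
name: bBMA
eta0_Pa_s: 25.58
gammadot_c_per_s: 1688
c: 0.561
Ea_J_per_mol: 140336
T_ref_K: 473
rho_bulk_kg_m3: 339
rho_true_kg_m3: 1092
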