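# Soluplus (polyvinyl caprolactam-polyvinyl acetate-PEG graft copolymer).
name: SOL
eta0_Pa_s: 147.3
gammadot_c_per_s: 136.7
c: 0.411
Ea_J_per_mol: 150773
T_ref_K: 473
rho_bulk_kg_m3: 597
rho_true_kg_m3: 1080
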