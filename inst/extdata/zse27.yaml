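# 27 mm class corotating twin-screw extruder with a 3 mm x 11.7 mm
# cylindrical die. Feeding-section pitch assumes square-pitched (1 D)
# conveying elements; nominal speed is the machine rating.
d_m: 0.0283
A_free_m2: 4.91e-4
l_pitch_m: 0.0283
r_die_m: 0.0015
l_die_m: 0.0117
n_max_rpm: 1200
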