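name,g_f_scale,shift_yinf_mV,shift_tau_mV,shift_iso_extra_mV,fixed_kinetics,expression_system,recording_temperature,source
R375C,0.5,-14,-14,0,FALSE,CHO,room,Alonso-Fernandez-Gatta et al.
R378C,0.43,-7.9,-7.9,0,FALSE,Xenopus oocytes,room,Moller et al.
A414G,1,-19.9,-11.9,0,FALSE,CHO,36C,Milano et al.
G480R,0.46,-10,-10,0,FALSE,Xenopus oocytes,room,Nof et al.
Y481H,1,-44,-44,0,FALSE,CHO,37C,Milano et al.
G482R_a,1,-39,-39,0,FALSE,CHO,37C,Milano et al.
G482R_b,0.35,0,0,0,FALSE,HEK-293,room,Schweizer et al.
A485V,0.32,-15,-15,0,FALSE,Xenopus oocytes,room,Laish-Farkash et al.
K530N,1,-14,-14,5,FALSE,HEK-293,room,Duhme et al.
R550C,1,-4,-4,0,FALSE,CHO/NRVC,room/36C,Campostrini et al.
R666Q,0.46,0,0,0,FALSE,HEK-293T,room,Wang et al.
S672R,1,-4.9,-4.9,0,FALSE,HEK-293,room,Milanesi et al.
695X,1,-10.9,-10.9,0,TRUE,HEK-293,room,Schweizer et al.
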