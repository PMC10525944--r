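name,qf_pC
WT,1.003
R375C,0.201
R378C,0.260
A414G,0.249
G480R,0.242
Y481H,0.046
G482R_a,0.066
G482R_b,0.351
A485V,0.120
K530N,0.401
R550C,0.780
R666Q,0.461
S672R,0.736
695X,0.495
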