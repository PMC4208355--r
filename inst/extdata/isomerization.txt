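# two-state isomerization of 4 molecules (binomial equilibrium)
S2 -> S1 ; k=1
S1 -> S2 ; k=2
init: S1=0 S2=4
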