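# constitutive production and degradation (Poisson equilibrium)
0 -> S ; k=1
S -> 0 ; k=1
init: S=0
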