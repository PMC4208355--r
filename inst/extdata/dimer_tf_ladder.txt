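# gene regulated by dimer TFs, T=8 monomers (ladder state space)
2 M -> D ; k=1
D -> 2 M ; k=1
D + G -> Gs ; k=1
Gs -> D + G ; k=1
init: M=8 D=0 G=1 Gs=0
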