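# 3 independent sites compounded over occupancy (equivalent N-copy chain)
G + F -> Gs ; k=1
Gs -> G + F ; k=1
init: G=3 Gs=0 F=6
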