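# gene with two ordered TF binding sites (three-state path)
G0 + F -> G1 ; k=1
G1 -> G0 + F ; k=1
G1 + F -> G2 ; k=1
G2 -> G1 + F ; k=1
init: G0=1 G1=0 G2=0 F=4
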