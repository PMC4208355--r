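# protein dimerization, 7 monomers (odd branch)
2 M -> D ; k=1
D -> 2 M ; k=2
init: M=7 D=0
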