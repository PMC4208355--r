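# gene with two independent TF binding sites (four-state cycle)
G00 + F -> G10 ; k=1
G10 -> G00 + F ; k=1
G00 + F -> G01 ; k=1
G01 -> G00 + F ; k=1
G10 + F -> G11 ; k=1
G11 -> G10 + F ; k=1
G01 + F -> G11 ; k=1
G11 -> G01 + F ; k=1
init: G00=1 G10=0 G01=0 G11=0 F=4
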