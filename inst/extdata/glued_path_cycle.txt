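# three TFBSs: unique first site, then two independent (path glued to cycle)
G0 + F -> GA ; k=1
GA -> G0 + F ; k=1
GA + F -> GAB ; k=1
GAB -> GA + F ; k=1
GA + F -> GAC ; k=1
GAC -> GA + F ; k=1
GAB + F -> GABC ; k=1
GABC -> GAB + F ; k=1
GAC + F -> GABC ; k=1
GABC -> GAC + F ; k=1
init: G0=1 GA=0 GAB=0 GAC=0 GABC=0 F=5
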