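# three TFBSs: two independent first, then unique third (cycle glued to path)
G0 + F -> GA ; k=1
GA -> G0 + F ; k=1
G0 + F -> GB ; k=1
GB -> G0 + F ; k=1
GA + F -> GAB ; k=1
GAB -> GA + F ; k=1
GB + F -> GAB ; k=1
GAB -> GB + F ; k=1
GAB + F -> GABC ; k=1
GABC -> GAB + F ; k=1
init: G0=1 GA=0 GB=0 GAB=0 GABC=0 F=5
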