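# single gene bound by one of 3 TFs (Bernoulli / Hill coefficient 1)
G + F -> Gs ; k=1
Gs -> G + F ; k=1
init: G=1 Gs=0 F=3
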