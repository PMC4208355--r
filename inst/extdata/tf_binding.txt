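# TF binding to 2 gene copies by 5 TFs (finite path)
G + F -> Gs ; k=1
Gs -> G + F ; k=1
init: G=2 Gs=0 F=5
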