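term	FX	FA	FB
dG_bkbn	15.10	17.03	16.61
ddG_rxn	79.99	75.70	76.27
dG_resd	-104.32	-96.66	-91.77
dEm	12.81	4.35	4.14
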