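cluster	d1	d2	d3	d4	avg_printed
FX	2.46	2.44	2.44	2.35	2.42
FA	2.46	2.48	2.52	2.34	2.45
FB	2.44	2.49	2.5	2.35	2.45
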