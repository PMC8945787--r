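cluster	em_calc_mV	em_sol_mV
FX	-715	-170
FA	-355	-170
FB	-346	-170
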