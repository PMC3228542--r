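species	n_ppis
Human	63010
Mouse	3331
HIV	2295
Rat	870
Others	1994
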