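H1	H2	H3	n_abba	n_baba	D	SE	Z
H. cyanocinctus	H. spiralis	H. melanocephalus	183151	166251	0.048368	0.003149	15.36
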