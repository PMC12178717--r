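species	locality	called_sites	het_sites	heterozygosity
H. curtus	South China Sea	538569068	980917	0.001821339
H. elegans	Western Australia	585587290	856186	0.001462098
H. ornatus	Okinawa Is., Japan	543339950	355153	0.000653648
H. melanocephalus	Okinawa Is., Japan	585539300	725281	0.001238655
H. cyanocinctus	South China Sea	579837364	820510	0.001415069
H. stokesii	Okinawa Is., Japan	539548082	55782	0.000103387
H. stokesii	Exmouth, Australia	550759750	466195	0.000846458
H. atriceps	Gulf of Thailand	578891733	1176941	0.002033093
H. kingii	Broome, Australia	572189301	549314	0.000960021
H. major	Broome, Australia	561626452	719192	0.001280552
H. ocellatus	Broome, Australia	559502620	685963	0.001226023
H. peronii	Pibara, Australia	545612477	451757	0.000827981
H. platurus	Mannar, Sri Lanka	557966852	822116	0.001473414
H. schistosus	Penang, Malaysia	568993188	620794	0.001091039
H. schistosus	Puttlam, Sri Lanka	562804344	310424	0.000551566
H. spiralis	Gulf of Thailand	573066168	911107	0.001589881
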