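accession	exposure	n_snp	n_sample	r2_pct	f_stat
ukb-a-25	Alcohol intake frequency	44	336965	0.78	59.85
ukb-b-11348	Bread intake	32	452236	0.30	41.93
ukb-b-1489	Cheese intake	65	460006	0.56	39.23
ukb-b-15926	Cereal intake	43	451486	0.44	45.22
ukb-b-16576	Dried fruit intake	43	441640	0.43	42.07
ukb-b-3881	Fresh fruit intake	55	421764	0.57	46.20
ukb-b-17627	Non-oily fish intake	11	460880	0.11	44.84
ukb-b-2209	Oily fish intake	63	435435	0.61	45.18
ukb-b-1996	Raw vegetable intake	22	460443	0.19	38.40
ukb-b-8089	Cooked vegetable intake	17	461053	0.14	37.63
ukb-b-2862	Beef intake	17	446462	0.15	41.53
ukb-b-5640	Pork intake	14	428860	0.11	37.72
ukb-b-14179	Lamb intake	32	460162	0.28	39.70
ukb-b-6324	Processed meat intake	23	447485	0.19	38.60
ukb-b-8006	Poultry intake	8	461981	0.06	32.55
ukb-b-5237	Coffee intake	40	461900	0.68	73.15
ukb-b-6066	Tea intake	41	448651	0.56	61.12
ukb-b-8121	Salt added to food	106	462630	1.15	50.77
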