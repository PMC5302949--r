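snp_id	gene	model	case_ref	case_het	case_hom	ctrl_ref	ctrl_het	ctrl_hom	case_exposed	case_unexposed	ctrl_exposed	ctrl_unexposed	or_printed	ci_low_printed	ci_high_printed	p_max	q_printed	boot_p05	boot_p01	boot_p001
rs11152377	BCL-2	recessive	NA	NA	53	NA	NA	91	53	364	91	326	0.53	0.37	0.77	0.001	0.037	100	99	49
rs135014	BIK	additive	150	199	68	119	189	106	NA	NA	NA	NA	0.73	0.60	0.89	0.001	0.037	100	99	32
rs16957730	TP53BP1	dominant	308	NA	NA	268	NA	NA	108	308	149	268	0.63	0.47	0.85	0.002	0.037	100	95	28
rs2889	TNFRSF10B	dominant	167	NA	NA	209	NA	NA	249	167	208	209	1.53	1.16	2.02	0.002	0.037	100	97	25
rs17782975	TP53BP1	dominant	378	NA	NA	348	NA	NA	39	378	69	348	0.53	0.35	0.81	0.003	0.037	100	92	16
rs1801018	BCL-2	recessive	NA	NA	64	NA	NA	99	64	353	99	318	0.60	0.42	0.85	0.004	0.037	100	81	6
rs744120	BIRC5	recessive	NA	NA	23	NA	NA	43	23	394	43	373	0.45	0.26	0.78	0.004	0.037	100	74	3
rs1016860	BCL-2	additive	348	66	2	322	84	10	NA	NA	NA	NA	0.63	0.46	0.87	0.005	0.037	100	91	11
rs4941183	BCL-2	recessive	NA	NA	77	NA	NA	111	77	340	111	306	0.63	0.45	0.88	0.007	0.045	100	75	6
rs4988360	BIK	dominant	337	NA	NA	302	NA	NA	80	337	115	302	0.64	0.46	0.89	0.007	0.045	100	80	1
rs5759167	BIK	recessive	NA	NA	78	NA	NA	112	78	339	112	305	0.64	0.46	0.89	0.008	0.045	100	57	2
rs1001793	TNFRSF10B	recessive	NA	NA	37	NA	NA	57	37	363	57	338	0.54	0.35	0.86	0.008	0.046	100	56	3
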