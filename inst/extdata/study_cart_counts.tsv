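node	case_n	control_n	or_printed	ci_low_printed	ci_high_printed	p_max
1	15	46	1	NA	NA	NA
2	12	30	1.25	0.51	3.03	0.629
3	8	16	1.58	0.56	4.42	0.388
4	9	17	1.42	0.51	3.94	0.501
5	27	40	1.79	0.82	3.91	0.143
6	37	45	2.53	1.22	5.24	0.012
7	55	63	2.67	1.34	5.31	0.005
8	60	46	3.94	1.95	7.92	0.001
9	185	104	5.40	2.86	10.16	0.001
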