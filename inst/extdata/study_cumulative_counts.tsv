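group	label	case_n	control_n	or_printed	ci_low_printed	ci_high_printed	p_max
1	3~7	21	74	1	NA	NA	NA
2	8~9	115	156	2.62	1.52	4.51	0.001
3	10	110	91	4.25	2.43	7.45	0.001
4	11~12	151	74	7.42	4.23	13.04	0.001
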