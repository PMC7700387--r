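gene	utr_length	n_uatg	n_uorf	n_intron	n_rg4	n_stem_loops	n_all_elements	tissue_distribution	mode_expression
ABCA3	694	4	2	3	1	5	13	3	3
ABCA1	313	1	1	1	1	6	9	4	3
ABCA4	103	1	0	0	0	2	3	1	4
ABCA5	97	0	0	1	0	4	5	4	4
ABCA10	910	14	6	3	0	5	22	3	3
ABCA6	196	2	0	1	0	3	6	4	2
ABCA12	418	4	1	0	0	6	10	3	3
ABCA13	26	0	0	0	0	0	0	NA	NA
ABCA9	75	3	2	1	0	2	6	4	4
ABCA8	340	6	2	2	0	3	11	2	2
ABCA7	227	1	1	1	1	3	6	3	2
ABCA2	97	1	1	0	1	2	4	3	3
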