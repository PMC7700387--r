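gene	uatg_index	pos	conservation_category	context_category	tis_bin
ABCA3	1	-525	3	2	3
ABCA3	2	-498	4	1	3
ABCA3	3	-329	1	2	2
ABCA3	4	-262	1	1	2
ABCA1	1	-89	5	1	2
ABCA4	1	-62	3	1	1
ABCA10	1	-755	1	2	2
ABCA10	2	-722	1	2	2
ABCA10	3	-709	1	1	2
ABCA10	4	-645	4	2	3
ABCA10	5	-625	1	1	2
ABCA10	6	-574	1	1	2
ABCA10	7	-571	0	2	2
ABCA10	8	-482	1	2	2
ABCA10	9	-464	3	3	2
ABCA10	10	-279	3	1	2
ABCA10	11	-265	3	3	3
ABCA10	12	-197	3	3	2
ABCA10	13	-169	3	3	2
ABCA10	14	-56	3	1	1
ABCA6	1	-144	3	2	2
ABCA6	2	-32	1	2	1
ABCA12	1	-398	1	2	2
ABCA12	2	-333	4	1	2
ABCA12	3	-330	1	2	2
ABCA12	4	-115	4	2	2
ABCA9	1	-70	3	2	1
ABCA9	2	-58	1	2	1
ABCA9	3	-54	3	1	1
ABCA8	1	-265	0	2	2
ABCA8	2	-243	1	2	3
ABCA8	3	-152	0	2	2
ABCA8	4	-149	0	2	2
ABCA8	5	-135	0	2	2
ABCA8	6	-79	0	2	1
ABCA7	1	-103	3	2	2
ABCA2	1	-88	2	2	1
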