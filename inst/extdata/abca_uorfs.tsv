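gene	uorf_index	start	end	open_ended	length_nt	riboseq_cov
ABCA3	1	-525	-376	FALSE	150	3
ABCA3	2	-262	NA	TRUE	261	2
ABCA1	1	-89	NA	TRUE	87	3
ABCA10	1	-722	-690	FALSE	33	1
ABCA10	2	-625	-509	FALSE	117	1
ABCA10	3	-482	-441	FALSE	42	1
ABCA10	4	-279	-247	FALSE	33	1
ABCA10	5	-265	-95	FALSE	171	1
ABCA10	6	-197	-159	FALSE	39	1
ABCA12	1	-398	-330	FALSE	69	1
ABCA9	1	-70	-38	FALSE	33	1
ABCA9	2	-54	-16	FALSE	39	1
ABCA8	1	-243	-205	FALSE	39	3
ABCA8	2	-79	-5	FALSE	75	1
ABCA7	1	-103	NA	TRUE	102	3
ABCA2	1	-88	-23	FALSE	66	1
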