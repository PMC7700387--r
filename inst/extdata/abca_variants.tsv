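gene	rsid	pos	ref	alt	type	strand
ABCA1	rs1800978	-18	C	G	SNV	-
ABCA1	rs1799777	-77	C	CC	indel	-
ABCA1	rs111292742	-279	G	C	SNV	-
ABCA3	rs45487892	-67	G	A	SNV	-
ABCA3	rs45518738	-182	G	A	SNV	-
ABCA3	rs146642275	-397	G	A	SNV	-
ABCA3	rs1029783163	-409	G	A	SNV	-
ABCA7	rs182233998	-14	T	C	SNV	+
ABCA7	rs3752229	-9	A	G	SNV	+
ABCA10	rs1024510317	-89	G	C	SNV	-
ABCA10	rs9302891	-438	G	T	SNV	-
ABCA10	rs1238052530	-482	T	C	SNV	-
ABCA10	rs563620435	-762	C	A	SNV	-
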