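gene	intron_index	length
ABCA3	1	10718
ABCA3	2	890
ABCA3	3	1960
ABCA1	1	24163
ABCA5	1	12621
ABCA10	1	15668
ABCA10	2	1295
ABCA10	3	1615
ABCA6	1	996
ABCA9	1	9726
ABCA8	1	5746
ABCA8	2	7272
ABCA7	1	1028
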