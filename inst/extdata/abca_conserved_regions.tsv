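gene	start	end
ABCA3	-519	-503
ABCA1	-119	-59
ABCA4	-65	-50
ABCA5	-7	-2
ABCA10	-459	-368
ABCA6	-156	-63
ABCA8	-234	-180
ABCA7	-137	-73
ABCA2	-65	-12
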