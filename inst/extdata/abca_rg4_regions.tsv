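gene	start	end
ABCA3	-608	-576
ABCA1	-251	-218
ABCA7	-217	-158
ABCA2	-81	-34
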