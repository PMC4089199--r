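class	globin	ras	trypsin
globin	73	1	1
ras	2	71	2
trypsin	2	1	72
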