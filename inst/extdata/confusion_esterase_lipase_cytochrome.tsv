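class	esterase	lipase	cytochrome
esterase	51	2	4
lipase	2	42	1
cytochrome	2	1	39
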