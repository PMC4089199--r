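class	metabolism	transcription	cellular_transport
metabolism	201	9	15
transcription	6	142	8
cellular_transport	17	14	137
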