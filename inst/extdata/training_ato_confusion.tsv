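observed	MFO	OLV	ORT	POP
MFO	8	0	0	0
OLV	0	18	0	0
ORT	0	0	13	0
POP	0	0	0	8
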