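COLAG	I-1	0	0	2	2
COLAG	I-2	0	0	1	1
COLAG	II-1	I-2	I-1	2	2
COLAG	II-2	0	0	1	1
COLAG	III-1	II-2	II-1	1	2
COLAG	III-2	II-2	II-1	2	1
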