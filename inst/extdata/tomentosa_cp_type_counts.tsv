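type	MBJ	MHBJ	MHN	SXJ	MSXQ	MGS	AH
mb1	28	46	55	42	34	6	6
mb2	9	7	0	1	1	0	0
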