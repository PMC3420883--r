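gene	mutation	indel_length	alt_start	interval_start	interval_end	count_western	n_western	count_eastern	n_eastern	count_central	n_central	count_nc	n_nc
cTAS2R1	del	1	0	NA	NA	22	92	0	20	0	4	0	2
cTAS2R3	LIC	NA	1	NA	NA	75	92	20	20	4	4	2	2
cTAS2R7	GTC	NA	0	NA	NA	0	92	0	20	1	4	0	2
cTAS2R30	ins	19	0	NA	NA	3	92	0	20	0	4	0	2
cTAS2R31	GTC	NA	0	NA	NA	9	92	0	20	0	4	0	2
cTAS2R38	LIC	NA	0	NA	NA	70	92	0	20	0	4	0	2
cTAS2R40	GTC	NA	0	NA	NA	0	92	1	20	0	4	0	2
cTAS2R42	del	5	0	NA	NA	24	92	10	20	1	4	1	2
cTAS2R43	ins	1	0	NA	NA	11	92	0	20	0	4	0	2
cTAS2R43	LIC	NA	0	NA	NA	0	92	3	20	0	4	0	2
cTAS2R43	WGD	NA	0	NA	NA	0	92	3	20	0	4	0	2
cTAS2R45	del	4	0	NA	NA	11	92	0	20	0	4	0	2
cTAS2R45	LIC	NA	0	NA	NA	0	92	0	20	3	4	0	2
cTAS2R46	GTC	NA	0	NA	NA	0	92	3	20	0	4	0	2
cTAS2R46	WGD	NA	0	NA	NA	0	92	3	20	0	4	0	2
cTAS2R46	GC	NA	0	514	586	0	92	0	20	0	4	1	2
cTAS2R60	del	2	0	NA	NA	0	92	0	20	2	4	1	2
cTAS2R64	WGD	NA	0	NA	NA	0	92	3	20	0	4	0	2
cTAS2R64	GC	NA	0	141	273	0	92	2	20	0	4	0	2
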