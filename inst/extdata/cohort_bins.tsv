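group	region	b0	b1	b2	bgt2
NNb	SMN1_e7	0	0	60	62
NNb	SMN1_e8	1	0	54	67
NNb	SMN2_e7	15	20	73	14
NNb	SMN2_e8	33	55	31	3
NNb	NAIP_e5	0	0	76	46
NNb	RAD17	0	0	104	18
NNw	SMN1_e7	0	0	29	1
NNw	SMN1_e8	0	0	28	2
NNw	SMN2_e7	2	8	18	2
NNw	SMN2_e8	2	12	14	2
NNw	NAIP_e5	0	0	26	4
NNw	RAD17	0	0	30	0
M1M1b	SMN1_e7	75	0	0	0
M1M1b	SMN1_e8	38	22	12	3
M1M1b	SMN2_e7	0	4	63	8
M1M1b	SMN2_e8	8	15	49	3
M1M1w	SMN1_e7	30	0	0	0
M1M1w	SMN1_e8	24	4	2	0
M1M1w	SMN2_e7	0	2	17	11
M1M1w	SMN2_e8	0	5	13	12
M2M2b	SMN1_e7	0	2	16	32
M2M2b	SMN1_e8	0	0	21	29
M2M2b	SMN2_e7	50	0	0	0
M2M2b	SMN2_e8	49	1	0	0
M2M2w	SMN1_e7	0	0	5	3
M2M2w	SMN1_e8	0	0	5	3
M2M2w	SMN2_e7	8	0	0	0
M2M2w	SMN2_e8	8	0	0	0
UUb	SMN1_e7	0	6	38	28
UUb	SMN1_e8	0	5	31	36
UUb	SMN2_e7	10	8	51	3
UUb	SMN2_e8	17	33	19	3
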