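gene	log2fc_a	log2fc_b	degree	neighborhood_connectivity
AQR	-1.67	0.9	92	85.59
EGFR	-1.77	0.26	92	24.63
ERBB2	-1.71	0.3	41	32.24
PTK2B	-1.33	-0.25	27	43.96
MAP2K1	-1.02	-0.18	24	31.58
ACTG1	1.42	-1.96	30	12.6
FOS	1.39	-2.26	25	27.08
LSM2	0.1	1.25	101	79.47
FAU	0.19	-1.59	72	67.29
PSME3	0.08	1.58	35	34.23
POLR2H	0.21	1.16	26	14.08
IRS2	-0.57	1.13	25	34.04
MCM5	-0.32	-1.44	24	22.67
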