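# Per-parent, per-chromosome linkage map summaries for 10 E. globulus parents.
# Units: total_cm in centimorgans (Haldane); phys_mb in megabases (anchored span);
# mean_rr in cM/Mb as printed (2 decimals). interval_count = number of marker intervals.
parent_id	cross_type	sex	chromosome	interval_count	total_cm	phys_mb	mean_rr
F1.1-F	F1	female	1	8	122	36.1	3.38
F1.1-F	F1	female	2	8	170	58.0	2.93
F1.1-F	F1	female	3	15	174	67.6	2.57
F1.1-F	F1	female	4	6	99	40.6	2.44
F1.1-F	F1	female	5	17	125	71.0	1.76
F1.1-F	F1	female	6	10	199	52.6	3.78
F1.1-F	F1	female	7	12	147	51.7	2.84
F1.1-F	F1	female	8	11	206	64.7	3.19
F1.1-F	F1	female	9	10	132	37.2	3.55
F1.1-F	F1	female	10	5	91	26.5	3.44
F1.1-F	F1	female	11	8	122	41.5	2.94
F1.1-M	F1	male	1	7	150	38.1	3.93
F1.1-M	F1	male	2	10	176	54.8	3.21
F1.1-M	F1	male	3	16	159	73.0	2.18
F1.1-M	F1	male	4	8	82	34.1	2.40
F1.1-M	F1	male	5	11	129	72.3	1.78
F1.1-M	F1	male	6	10	173	49.2	3.52
F1.1-M	F1	male	7	9	105	41.8	2.51
F1.1-M	F1	male	8	14	128	56.4	2.27
F1.1-M	F1	male	9	8	99	35.1	2.82
F1.1-M	F1	male	10	4	113	29.1	3.88
F1.1-M	F1	male	11	9	139	42.3	3.29
F1.4-F	F1	female	1	8	176	37.4	4.71
F1.4-F	F1	female	2	9	199	55.3	3.60
F1.4-F	F1	female	3	19	184	75.8	2.43
F1.4-F	F1	female	4	6	98	36.0	2.72
F1.4-F	F1	female	5	16	145	72.3	2.01
F1.4-F	F1	female	6	9	183	45.3	4.04
F1.4-F	F1	female	7	13	180	49.9	3.61
F1.4-F	F1	female	8	13	224	59.3	3.77
F1.4-F	F1	female	9	8	118	34.3	3.44
F1.4-F	F1	female	10	3	117	25.4	4.61
F1.4-F	F1	female	11	12	163	43.9	3.72
F1.4-M	F1	male	1	9	153	39.3	3.90
F1.4-M	F1	male	2	10	144	51.8	2.78
F1.4-M	F1	male	3	17	142	74.5	1.91
F1.4-M	F1	male	4	4	110	34.9	3.15
F1.4-M	F1	male	5	12	143	66.3	2.16
F1.4-M	F1	male	6	8	154	38.9	3.96
F1.4-M	F1	male	7	12	115	51.2	2.25
F1.4-M	F1	male	8	16	177	71.9	2.46
F1.4-M	F1	male	9	6	82	33.5	2.45
F1.4-M	F1	male	10	7	99	31.0	3.19
F1.4-M	F1	male	11	16	137	41.5	3.30
F1.5-F	F1	female	1	7	115	34.4	3.35
F1.5-F	F1	female	2	7	142	47.9	2.96
F1.5-F	F1	female	3	17	136	67.9	2.00
F1.5-F	F1	female	4	7	101	35.6	2.84
F1.5-F	F1	female	5	10	109	59.4	1.84
F1.5-F	F1	female	6	9	165	40.2	4.11
F1.5-F	F1	female	7	11	152	51.9	2.93
F1.5-F	F1	female	8	14	170	65.3	2.60
F1.5-F	F1	female	9	9	104	36.1	2.88
F1.5-F	F1	female	10	9	104	27.6	3.77
F1.5-F	F1	female	11	11	144	42.1	3.42
F1.5-M	F1	male	1	6	139	31.6	4.40
F1.5-M	F1	male	2	14	157	56.8	2.76
F1.5-M	F1	male	3	12	184	71.6	2.57
F1.5-M	F1	male	4	7	116	35.7	3.25
F1.5-M	F1	male	5	12	166	71.0	2.34
F1.5-M	F1	male	6	11	181	52.6	3.44
F1.5-M	F1	male	7	8	173	51.1	3.38
F1.5-M	F1	male	8	10	206	66.4	3.10
F1.5-M	F1	male	9	7	109	36.7	2.97
F1.5-M	F1	male	10	11	136	32.1	4.24
F1.5-M	F1	male	11	11	151	42.3	3.57
F2.J-F	F2	female	1	6	107	36.1	2.96
F2.J-F	F2	female	2	13	167	56.0	2.98
F2.J-F	F2	female	3	17	139	76.1	1.83
F2.J-F	F2	female	4	8	101	36.7	2.75
F2.J-F	F2	female	5	14	129	69.7	1.85
F2.J-F	F2	female	6	11	163	43.3	3.76
F2.J-F	F2	female	7	10	101	47.2	2.14
F2.J-F	F2	female	8	15	158	66.4	2.38
F2.J-F	F2	female	9	9	105	34.8	3.02
F2.J-F	F2	female	10	10	162	36.7	4.42
F2.J-F	F2	female	11	10	168	43.4	3.87
F2.J-M	F2	male	1	10	129	36.1	3.57
F2.J-M	F2	male	2	9	165	55.0	3.00
F2.J-M	F2	male	3	17	153	75.4	2.03
F2.J-M	F2	male	4	12	92	32.3	2.85
F2.J-M	F2	male	5	13	141	72.9	1.93
F2.J-M	F2	male	6	14	164	53.1	3.09
F2.J-M	F2	male	7	14	142	52.3	2.71
F2.J-M	F2	male	8	15	181	71.7	2.52
F2.J-M	F2	male	9	8	121	37.5	3.23
F2.J-M	F2	male	10	14	130	33.2	3.92
F2.J-M	F2	male	11	16	124	42.7	2.90
F2.C-F	F2	female	1	5	105	35.0	3.00
F2.C-F	F2	female	2	13	164	61.1	2.68
F2.C-F	F2	female	3	16	160	69.7	2.30
F2.C-F	F2	female	4	9	110	38.0	2.90
F2.C-F	F2	female	5	14	144	67.0	2.15
F2.C-F	F2	female	6	15	168	52.2	3.22
F2.C-F	F2	female	7	10	133	51.1	2.60
F2.C-F	F2	female	8	14	137	64.7	2.12
F2.C-F	F2	female	9	11	117	38.0	3.08
F2.C-F	F2	female	10	9	120	35.0	3.43
F2.C-F	F2	female	11	8	118	42.3	2.79
F2.C-M	F2	male	1	6	119	32.6	3.65
F2.C-M	F2	male	2	11	172	61.5	2.80
F2.C-M	F2	male	3	18	139	76.2	1.82
F2.C-M	F2	male	4	11	92	39.1	2.35
F2.C-M	F2	male	5	12	136	69.4	1.96
F2.C-M	F2	male	6	12	189	52.0	3.64
F2.C-M	F2	male	7	14	121	50.3	2.41
F2.C-M	F2	male	8	17	178	72.3	2.46
F2.C-M	F2	male	9	8	102	38.3	2.66
F2.C-M	F2	male	10	8	113	35.6	3.18
F2.C-M	F2	male	11	12	124	42.3	2.93
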