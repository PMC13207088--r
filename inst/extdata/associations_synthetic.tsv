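# Synthetic gene-disease association table: 64 PD rows passing the
# stringent tier (score >= 0.8, EI >= 0.4) and 17 CKD rows passing the
# balanced tier (score >= 0.6, EI >= 0.4). The named symbols are the bridge
# and hub genes discussed in the documentation; fillers are synthetic.
gene	disease	score	ei
TNF	PD	0.87	0.53
INS	PD	0.94	0.66
IL6	PD	0.81	0.79
SNCA	PD	0.88	0.92
IL1B	PD	0.95	0.49
AKT1	PD	0.82	0.62
IGF2	PD	0.89	0.75
SOD1	PD	0.96	0.88
MAPK1	PD	0.83	0.45
TP53	PD	0.90	0.58
PDFILL01	PD	0.97	0.71
PDFILL02	PD	0.84	0.84
PDFILL03	PD	0.91	0.41
PDFILL04	PD	0.98	0.54
PDFILL05	PD	0.85	0.67
PDFILL06	PD	0.92	0.80
PDFILL07	PD	0.99	0.93
PDFILL08	PD	0.86	0.50
PDFILL09	PD	0.93	0.63
PDFILL10	PD	0.80	0.76
PDFILL11	PD	0.87	0.89
PDFILL12	PD	0.94	0.46
PDFILL13	PD	0.81	0.59
PDFILL14	PD	0.88	0.72
PDFILL15	PD	0.95	0.85
PDFILL16	PD	0.82	0.42
PDFILL17	PD	0.89	0.55
PDFILL18	PD	0.96	0.68
PDFILL19	PD	0.83	0.81
PDFILL20	PD	0.90	0.94
PDFILL21	PD	0.97	0.51
PDFILL22	PD	0.84	0.64
PDFILL23	PD	0.91	0.77
PDFILL24	PD	0.98	0.90
PDFILL25	PD	0.85	0.47
PDFILL26	PD	0.92	0.60
PDFILL27	PD	0.99	0.73
PDFILL28	PD	0.86	0.86
PDFILL29	PD	0.93	0.43
PDFILL30	PD	0.80	0.56
PDFILL31	PD	0.87	0.69
PDFILL32	PD	0.94	0.82
PDFILL33	PD	0.81	0.95
PDFILL34	PD	0.88	0.52
PDFILL35	PD	0.95	0.65
PDFILL36	PD	0.82	0.78
PDFILL37	PD	0.89	0.91
PDFILL38	PD	0.96	0.48
PDFILL39	PD	0.83	0.61
PDFILL40	PD	0.90	0.74
PDFILL41	PD	0.97	0.87
PDFILL42	PD	0.84	0.44
PDFILL43	PD	0.91	0.57
PDFILL44	PD	0.98	0.70
PDFILL45	PD	0.85	0.83
PDFILL46	PD	0.92	0.40
PDFILL47	PD	0.99	0.53
PDFILL48	PD	0.86	0.66
PDFILL49	PD	0.93	0.79
PDFILL50	PD	0.80	0.92
PDFILL51	PD	0.87	0.49
PDFILL52	PD	0.94	0.62
PDFILL53	PD	0.81	0.75
PDFILL54	PD	0.88	0.88
FN1	CKD	0.71	0.57
APOA1	CKD	0.82	0.74
UMOD	CKD	0.93	0.91
ACE	CKD	0.64	0.52
WT1	CKD	0.75	0.69
CKDFILL01	CKD	0.86	0.86
CKDFILL02	CKD	0.97	0.47
CKDFILL03	CKD	0.68	0.64
CKDFILL04	CKD	0.79	0.81
CKDFILL05	CKD	0.90	0.42
CKDFILL06	CKD	0.61	0.59
CKDFILL07	CKD	0.72	0.76
CKDFILL08	CKD	0.83	0.93
CKDFILL09	CKD	0.94	0.54
CKDFILL10	CKD	0.65	0.71
CKDFILL11	CKD	0.76	0.88
CKDFILL12	CKD	0.87	0.49
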