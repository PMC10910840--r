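population	sample	ab	ac	bc	yx	yw	xw	ay	bx	cw
KAT	KAT7	0.91	1.00	0.30	1.28	2.51	2.61	5.51	4.72	4.60
KAT	KAT8	1.01	1.09	0.31	1.27	2.52	2.66	5.96	5.13	4.94
KAT	KAT9	0.87	0.95	0.26	1.09	2.03	2.15	5.07	4.27	4.19
KAT	KAT10	0.88	0.99	0.31	1.31	2.63	2.74	5.52	4.78	4.63
KAT	KAT11	1.00	1.12	0.32	1.19	2.39	2.48	6.30	5.43	5.25
KAT	KAT12	1.01	1.12	0.31	1.31	2.54	2.68	5.32	4.36	4.17
SAI	SAI1	1.41	1.55	0.49	0.97	2.27	2.30	9.03	7.83	7.34
SAI	SAI2	1.29	1.50	0.49	1.08	2.61	2.65	9.00	7.91	7.39
SAI	SAI3	1.15	1.34	0.44	1.83	4.31	4.42	9.74	8.79	8.12
SAI	SAI4	1.42	1.59	0.50	1.94	4.51	4.62	10.37	9.43	8.69
SAI	SAI5	1.17	1.30	0.41	2.30	5.37	5.56	10.90	10.00	9.20
SAI	SAI12	1.23	1.36	0.42	0.87	1.99	2.06	8.43	7.31	6.86
SAI	SAI13	1.23	1.38	0.47	1.57	3.60	3.70	9.48	8.46	7.93
SAI	SAI14	1.43	1.56	0.50	1.20	2.85	2.90	9.62	8.43	7.80
SAI	SAI15	1.20	1.32	0.44	0.58	1.38	1.42	8.31	7.32	6.83
SAI	SAI16	1.21	1.42	0.45	1.07	2.40	2.44	8.24	7.12	6.65
SAI	SAI17	1.19	1.34	0.42	1.86	4.33	4.46	9.64	8.69	8.10
SAI	SAI18	1.23	1.38	0.46	1.54	3.65	3.77	9.48	8.51	7.86
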