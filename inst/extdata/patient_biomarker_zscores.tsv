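subject	group	z_nfq	rank_nfq	z_meta_roi	rank_meta_roi	z_left_hipp	rank_left_hipp	z_right_hipp	rank_right_hipp	z_inf_parietal	rank_inf_parietal
dAD1	dAD	4.15	1.00	-1.93	0.03	-0.41	0.34	1.08	0.86	-4.54	0.00
dAD2	dAD	-0.47	0.32	-0.36	0.36	-1.10	0.14	-0.64	0.26	0.52	0.70
dAD3	dAD	3.88	1.00	-2.86	0.00	-2.55	0.01	-1.01	0.16	-4.23	0.00
dAD4	dAD	0.81	0.79	-4.01	0.00	-1.87	0.03	-1.65	0.05	-3.31	0.00
dAD5	dAD	5.16	1.00	-0.81	0.21	-1.27	0.10	-0.50	0.31	-1.97	0.02
dAD6	dAD	3.50	1.00	0.12	0.55	1.35	0.91	1.77	0.96	-2.77	0.00
dAD7	dAD	1.98	0.98	0.09	0.54	-0.46	0.32	-0.75	0.23	-0.73	0.23
dAD8	dAD	1.81	0.97	-1.46	0.07	-0.94	0.17	0.25	0.60	-4.19	0.00
dAD9	dAD	1.31	0.90	-2.96	0.00	-1.47	0.07	-0.57	0.29	-7.36	0.00
dAD10	dAD	-0.07	0.47	-2.06	0.02	-1.86	0.03	-0.33	0.37	-3.45	0.00
AD1	AD	2.20	0.99	-2.80	0.00	-1.04	0.15	-1.51	0.07	-0.23	0.41
AD2	AD	3.46	1.00	-5.77	0.00	-1.54	0.06	-1.34	0.09	-1.35	0.09
AD3	AD	0.61	0.73	-1.87	0.03	-0.75	0.23	0.08	0.53	-2.45	0.01
AD4	AD	0.77	0.78	-3.34	0.00	-1.93	0.03	-1.65	0.05	-0.69	0.24
AD5	AD	2.65	1.00	-1.27	0.10	-3.42	0.00	-3.53	0.00	-3.03	0.00
AD6	AD	3.38	1.00	-0.12	0.45	-0.28	0.39	0.63	0.73	0.67	0.75
AD7	AD	1.90	0.97	-4.39	0.00	-1.43	0.08	-2.41	0.01	-0.63	0.27
AD8	AD	-0.91	0.18	-0.92	0.18	-1.89	0.03	-1.56	0.06	-3.47	0.00
CU1	control	1.07	0.86	-0.54	0.29	0.41	0.66	0.58	0.72	-0.92	0.18
CU2	control	0.53	0.70	0.33	0.63	-0.19	0.43	-0.26	0.40	-0.71	0.24
CU3	control	0.54	0.70	1.01	0.84	0.11	0.54	-0.06	0.47	1.69	0.95
CU4	control	-0.53	0.30	0.52	0.70	1.58	0.94	1.71	0.96	0.34	0.63
CU5	control	-0.57	0.29	2.31	0.99	1.35	0.91	1.84	0.97	-0.42	0.34
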