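year	management	trait	sigma2_g	sigma2_trial	sigma2_gxt	sigma2_e	h2_printed	mean	n_trials	n_reps
2017	WW	GY	0.17	0.48	0.00	2.23	0.68	6.05	14	2
2017	WW	AD	1.07	143.25	0.00	3.78	0.89	64.24	14	2
2017	WW	PH	34.30	1072.14	1.08	227.62	0.81	236.04	14	2
2017	WS	GY	0.08	NA	NA	0.76	0.17	3.28	1	2
2017	WS	AD	1.94	NA	NA	1.88	0.67	63.41	1	2
2017	WS	PH	34.56	NA	NA	190.87	0.27	209.03	1	2
2018	WW	GY	0.36	1.11	0.21	1.91	0.91	8.02	34	2
2018	WW	AD	1.33	149.85	0.63	2.68	0.96	66.68	34	2
2018	WW	PH	63.68	39.00	30.58	172.82	0.95	252.11	34	2
2018	WS	GY	0.25	NA	NA	0.50	0.50	3.11	1	2
2018	WS	AD	2.08	NA	NA	2.40	0.63	72.79	1	2
2018	WS	PH	79.27	NA	NA	117.84	0.57	212.09	1	2
2019	WW	GY	0.12	0.24	0.05	2.19	0.64	6.34	17	2
2019	WW	AD	0.57	115.35	0.05	4.12	0.82	65.75	17	2
2019	WW	PH	17.10	538.31	17.46	251.28	0.67	247.28	17	2
2019	WS	GY	0.07	NA	NA	0.61	0.18	2.29	1	2
2019	WS	AD	1.39	NA	NA	2.12	0.57	67.48	1	2
2019	WS	PH	27.82	NA	NA	187.59	0.23	213.87	1	2
pooled	WW	GY	0.19	0.00	0.14	2.10	0.91	6.69	65	2
pooled	WW	AD	0.80	83.11	0.59	3.33	0.96	65.55	65	2
pooled	WW	PH	35.26	509.71	25.12	210.71	0.95	243.96	65	2
pooled	WS	GY	0.12	0.25	0.04	0.61	0.96	2.89	3	2
pooled	WS	AD	0.94	21.97	1.08	2.05	0.97	67.90	3	2
pooled	WS	PH	40.82	0.00	12.46	159.48	0.97	211.91	3	2
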