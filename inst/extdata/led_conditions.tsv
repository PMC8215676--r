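intensity	uv	blue	green	red	far_red	E_I	ratio
50	0.04	15.22	22.65	12.94	1.08	11.13	4.49
100	0.06	28.94	46.02	26.00	2.11	22.88	4.37
150	0.12	43.48	68.51	38.77	3.31	34.01	4.41
200	0.16	58.04	91.18	51.18	4.40	44.91	4.45
250	0.19	73.19	113.21	63.72	5.27	56.29	4.44
300	0.24	87.16	136.47	76.85	6.26	67.81	4.42
350	0.23	101.00	159.52	89.82	7.30	78.68	4.45
400	0.28	117.86	181.02	101.54	8.11	90.14	4.44
450	0.40	134.02	202.89	113.80	9.40	101.14	4.45
500	0.37	148.36	225.24	126.93	10.42	111.79	4.47
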