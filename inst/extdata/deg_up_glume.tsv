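id	baseMean_wild	baseMean_cultivar	baseMean_landrace	log2fc_cw	padj_cw	log2fc_lw	padj_lw	annotation
Ta7asLoc021951.1	42.47	1189.91	717.98	4.81	1.80E-04	4.08	2.50E-03	3-ketoacyl-CoA synthase 12-like
Ta7bsLoc002749.1	2.79	306.18	109.26	6.78	5.12E-05	5.29	4.28E-03	3-ketoacyl-CoA synthase 12-like
Ta6asLoc018551.1	0.00	53.86	18.54	Inf	4.91E-04	Inf	2.85E-02	3-ketoacyl-CoA synthase
Ta7asLoc001384.1	20.78	591.48	521.17	4.83	1.59E-02	4.65	2.39E-02	3-ketoacyl-CoA synthase
Ta7bsLoc001848.1	14.15	363.40	330.26	4.68	5.37E-02	4.54	8.58E-02	3-ketoacyl-CoA synthase
Ta7bsLoc002750.1	14.74	443.97	186.17	4.91	3.14E-03	3.66	7.64E-02	3-ketoacyl-CoA synthase
Ta7bsLoc005172.1	0.46	89.24	55.43	7.59	1.12E-02	6.90	3.76E-02	3-ketoacyl-CoA synthase
Ta7bsLoc011512.1	67.99	919.81	753.44	3.76	3.74E-03	3.47	1.19E-02	3-ketoacyl-CoA synthase
Ta6bsLoc008917.1	0.50	195.60	217.19	8.62	4.50E-10	8.77	3.18E-10	Chalcone synthase
Ta2bsLoc009111.1	0.46	1663.14	453.70	11.81	2.19E-16	9.93	5.54E-12	Chalcone synthase 8
Ta3bLoc000987.1	0.93	1583.66	2159.97	10.74	4.24E-22	11.18	2.26E-23	Chalcone synthase 8
Ta4bsLoc019947.2	0.00	51.71	97.56	Inf	8.90E-04	Inf	1.74E-04	Chalcone synthase 8
Ta6bsLoc002330.1	0.00	306.31	386.67	Inf	3.33E-19	Inf	2.60E-20	Chalcone synthase 8
Ta2alLoc009166.1	71.52	237.64	320.20	1.73	7.70E-03	2.16	6.86E-05	Amino acid permease 6
Ta2alLoc010251.2	11.86	139.49	88.59	3.56	0.00	2.90	6.08E-03	Amino acid permease-like protein
Ta5asLoc003267.1	28.62	147.37	107.71	2.36	0.00	1.91	2.31E-02	Amino acid permease
Ta1alLoc016727.3	36.90	268.40	132.25	2.86	2.30E-07	1.84	1.04E-02	Silicon transporter
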