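id	baseMean_wild	baseMean_cultivar	baseMean_landrace	log2fc_cw	padj_cw	log2fc_lw	padj_lw	annotation
Ta7alLoc001275.1	1093.35	416.13	388.49	-1.39	7.96E-03	-1.49	3.19E-03	4-coumarate:CoA ligase
Ta1blLoc007155.1	5137.83	1403.42	2048.36	-1.87	1.00E-05	-1.33	6.17E-03	Cellulose synthase
Ta5alLoc000723.1	1933.05	441.04	647.98	-2.13	7.97E-07	-1.58	6.55E-04	Cellulose synthase
Ta3bLoc028980.1	4678.25	1223.81	1929.83	-1.93	3.84E-04	-1.28	8.50E-02	Cellulose synthase
Ta4alLoc006547.1	177.41	0.00	0.00	-Inf	2.47E-15	-Inf	1.30E-17	CER1 protein
Ta4alLoc026069.1	550.15	0.00	0.00	-Inf	8.29E-26	-Inf	4.65E-29	CER1 protein
Ta1alLoc003924.2	40.98	1.82	0.39	-4.49	5.99E-02	-6.71	1.80E-03	Cinnamoyl CoA reductase
Ta3bLoc003710.1	5610.65	1515.59	1849.21	-1.89	0.0001	-1.60	0.0016	Fasciclin-like arabinogalactan protein 7
Ta3bLoc056384.1	25.40	0.00	0.00	-Inf	6.75E-02	-Inf	3.53E-02	Flavonol 4-sulfotransferase
Ta4alLoc006913.1	299.00	4.85	7.32	-5.95	1.64E-16	-5.35	1.08E-16	Flavonol 4-sulfotransferase
Ta5blLoc013288.1	944.48	181.67	269.42	-2.38	1.04E-07	-1.81	1.66E-04	NAC domain-containing protein 18
Ta6blLoc001596.1	1507.23	377.78	671.34	-2.00	8.20E-06	-1.17	5.04E-02	Pectin lyase-like protein
Ta3bLoc036242.1	251.80	34.64	32.65	-2.86	1.16E-03	-2.95	1.53E-04	Pectinacetylesterase family protein
Ta3bLoc019897.1	219.61	36.13	30.72	-2.60	1.40E-02	-2.84	4.83E-03	Pectinacetylesterase family protein
Ta2blLoc014498.1	719.00	118.04	306.22	-2.61	4.62E-08	-1.23	6.04E-02	Phenylalanine ammonia-lyase
Ta3bLoc024051.1	342.10	34.22	106.23	-3.32	4.41E-09	-1.69	1.19E-02	Phenylalanine ammonia-lyase
Ta7asLoc021287.1	3214.99	932.09	1145.19	-1.79	3.10E-02	-1.49	8.21E-02	Sucrose synthase 2
Ta6bsLoc005412.1	839.45	149.96	376.09	-2.48	3.87E-07	-1.16	8.73E-02	Sucrose:fructan-6-fructosyltransferase
Ta4alLoc019947.1	168.96	45.07	38.20	-1.91	1.72E-02	-2.14	5.10E-03	Fiber protein Fb34
Ta7bsLoc005648.1	161.29	39.24	43.95	-2.04	2.28E-02	-1.88	3.37E-02	Trichome birefringence-like 22
Ta4blLoc021918.2	235.61	19.18	49.36	-3.62	4.92E-08	-2.26	8.61E-04	Laccase
Ta4asLoc013789.1	939.60	192.99	304.20	-2.28	5.70E-07	-1.63	1.16E-03	Laccase 16
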