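variant_id	gene_id	chrom	pos	ref	alt	site_quality	call_missingness	reference_maf
tv01	geneA	1	1010	A	G	20.1	0	1e-05
tv02	geneA	1	1020	A	G	19.1	0.02	1e-05
tv03	geneA	1	1030	A	G	25.09	0.1	9e-04
tv04	geneA	1	1040	A	G	20	0.05	0.001
tv05	geneA	1	1050	A	G	15.05	0.12	0
tv06	geneA	1	1060	A	G	24.98	0.02	5e-04
tv07	geneA	1	1070	A	G	19.71	0.09	0
tv08	geneA	1	1080	A	G	14.83	0.3	0.001
tv09	geneA	1	1090	A	G	44.77	0.12	0.001
tv10	geneA	1	1100	A	G	14.93	0.09	0
tv11	geneA	1	1110	A	G	29.95	0.09	5e-04
tv12	geneA	1	1120	A	G	14.75	0.1	5e-04
tv13	geneA	1	1130	A	G	44.89	0.09	9e-04
tv14	geneA	1	1140	A	G	20	0.12	1e-05
tv15	geneA	1	1150	A	G	20.78	0.12	5e-04
tv16	geneA	1	1160	A	G	20.01	0.1	NA
tv17	geneA	1	1170	A	G	20.28	0.12	0.002
tv18	geneA	1	1180	A	G	60.26	0.1	0
tv19	geneA	1	1190	A	G	18.69	0	0.001
tv20	geneA	1	1200	A	G	14.62	0.05	0
tv21	geneA	1	1210	A	G	20.39	0.02	1e-05
tv22	geneA	1	1220	A	G	20.2	0.02	5e-04
tv23	geneA	1	1230	A	G	19.23	0.05	9e-04
tv24	geneA	1	1240	A	G	60.36	0.12	9e-04
tv25	geneA	1	1250	A	G	45.1	0	NA
tv26	geneB	1	1260	A	G	14.61	0.05	9e-04
tv27	geneB	1	1270	A	G	20.6	0	0.001
tv28	geneB	1	1280	A	G	60.18	0.09	0
tv29	geneB	1	1290	A	G	20.73	0.12	NA
tv30	geneB	1	1300	A	G	59.64	0	0.001
tv31	geneB	1	1310	A	G	29.71	0.02	9e-04
tv32	geneB	1	1320	A	G	44.72	0.05	5e-04
tv33	geneB	1	1330	A	G	15.39	0.12	9e-04
tv34	geneB	1	1340	A	G	44.77	0.1	9e-04
tv35	geneB	1	1350	A	G	19.34	0.09	0
tv36	geneB	1	1360	A	G	60.02	0.02	5e-04
tv37	geneB	1	1370	A	G	19.18	0.02	NA
tv38	geneB	1	1380	A	G	20.37	0.1	NA
tv39	geneB	1	1390	A	G	18.73	0	5e-04
tv40	geneB	1	1400	A	G	20.6	0.1	9e-04
tv41	geneB	1	1410	A	G	20	0.1	0.001
tv42	geneB	1	1420	A	G	24.96	0	0.002
tv43	geneB	1	1430	A	G	18.67	0.09	9e-04
tv44	geneB	1	1440	A	G	18.74	0.05	9e-04
tv45	geneB	1	1450	A	G	60.38	0.1	0.002
tv46	geneB	1	1460	A	G	45.18	0.3	5e-04
tv47	geneB	1	1470	A	G	19.09	0.12	NA
tv48	geneB	1	1480	A	G	20	0	1e-05
tv49	geneB	1	1490	A	G	20.18	0.1	9e-04
tv50	geneB	1	1500	A	G	19.99	0.09	1e-05
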