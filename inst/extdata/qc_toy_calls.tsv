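participant_id	variant_id	dosage	depth	allele_balance
P268	tv01	1	7	0.35
P486	tv01	1	6	0.14
P462	tv02	1	6	0.1
P524	tv02	1	30	0.17
P966	tv02	1	30	0.05
P196	tv03	1	8	0.15
P640	tv03	1	12	0.05
P514	tv04	1	7	0.1
P722	tv04	1	5	0.5
P801	tv05	1	30	0.5
P802	tv05	1	30	0.5
P260	tv06	1	12	0.14
P645	tv06	1	8	0.35
P074	tv07	1	5	0.17
P180	tv07	1	30	0.35
P172	tv08	1	6	0.17
P178	tv08	1	7	0.17
P678	tv08	1	5	0.35
P217	tv09	1	7	0.14
P670	tv10	1	6	0.15
P798	tv10	1	7	0.8
P221	tv11	1	7	0.2
P560	tv12	1	8	0.17
P644	tv12	1	6	0.05
P673	tv12	1	6	0.8
P056	tv13	1	7	0.8
P094	tv14	2	6	0.35
P289	tv14	1	5	0.17
P337	tv14	1	6	0.2
P136	tv15	1	8	0.15
P619	tv15	1	7	0.35
P952	tv15	1	7	0.15
P133	tv16	1	5	0.05
P351	tv17	1	8	0.05
P356	tv17	1	7	0.5
P168	tv18	2	30	0.1
P678	tv19	1	12	0.5
P673	tv20	1	30	0.8
P703	tv20	1	7	0.1
P263	tv21	1	8	0.35
P693	tv22	1	12	0.35
P821	tv22	1	8	0.1
P124	tv23	1	12	0.05
P040	tv24	2	12	0.8
P046	tv24	1	7	0.2
P446	tv24	1	12	0.2
P591	tv25	1	6	0.15
P624	tv25	1	5	0.14
P918	tv25	1	8	0.2
P038	tv26	1	8	0.15
P123	tv26	1	5	0.1
P653	tv26	2	8	0.1
P419	tv27	1	30	0.17
P498	tv27	2	12	0.17
P638	tv27	1	8	0.17
P096	tv28	1	12	0.05
P454	tv29	1	30	0.35
P803	tv30	2	30	0.5
P308	tv31	1	12	0.8
P773	tv31	1	12	0.1
P935	tv31	1	30	0.17
P667	tv32	2	5	0.05
P068	tv33	1	30	0.15
P200	tv33	1	30	0.35
P230	tv33	1	8	0.35
P434	tv34	1	12	0.8
P298	tv35	1	6	0.5
P606	tv36	1	8	0.2
P886	tv36	1	30	0.5
P975	tv36	1	30	0.05
P373	tv37	1	7	0.2
P687	tv38	1	6	0.5
P783	tv38	1	12	0.2
P842	tv38	1	8	0.14
P445	tv39	1	12	0.14
P702	tv39	1	7	0.8
P887	tv39	2	8	0.2
P007	tv40	1	5	0.8
P114	tv40	1	30	0.14
P405	tv40	1	30	0.35
P347	tv41	1	6	0.05
P392	tv41	1	7	0.17
P938	tv41	1	6	0.1
P090	tv42	1	30	0.17
P282	tv43	1	5	0.5
P444	tv44	1	30	0.05
P636	tv44	1	30	0.17
P754	tv44	2	7	0.8
P688	tv45	1	8	0.14
P915	tv46	1	6	0.8
P118	tv47	1	30	0.05
P013	tv48	1	6	0.8
P551	tv48	2	5	0.15
P647	tv48	1	12	0.8
P098	tv49	2	7	0.5
P824	tv49	1	7	0.05
P466	tv50	1	7	0.2
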