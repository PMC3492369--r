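disease	disease_id	disease_degree	gene_degrees	c_xy_ref	p1_ref	p2_ref	s_ref	w_ref
Disorders of Sex Development	MESH:D012734	5	CYP19A1:202;HSD17B3:27;LHB:83;LHCGR:34;NR3C1:189	7.48	17.21	27.02	22.04	17.1
Muscular Dystrophy, Facioscapulohumeral	MESH:D020391	9	CDKN1A:375;DCN:49;ELN:32;HSPA1B:84;LUM:25	5.42	12.51	27.77	20.21	12.45
Osteosarcoma	MESH:D012516	11	CYP3A4:414;FOLR1:39;JUN:305;NR1I2:216;TP53:458	4.88	11.27	22.54	16.91	11.38
Metabolic Syndrome X	MESH:D024821	16	ADIPOQ:89;CCL2:283;LEP:106;SHBG:48;TRIB3:51	3.96	9.19	26.3	18.36	10.27
Precancerous Conditions	MESH:D011230	20	CCND1:327;IRS1:47;MAPK8:200;MAPK9:109;PTGS2:521	3.46	8.05	23.44	15.74	8.19
Myocardial Reperfusion Injury	MESH:D015428	22	ADIPOG:89;EDN1:186;NOS2:456;PTEN:100;SLC8A1:31	3.25	7.59	25.19	16.39	7.75
Drug Hypersensitivity	MESH:D004342	22	ABCC2:204;HSPA1A:122;IL4:228;IL4RA:17;TNF:835	3.25	7.59	24.13	15.86	7.74
Limb Deformities, Congenital	MESH:D017880	25	CACNA1C:23;FGFR2:90;HOXA11:22;TBX3:21;TGFB2:70	2.98	6.98	30.32	18.98	7.41
Carcinoma	MESH:D002277	25	BCL2:443;EGFR:204;KRAS:79;PTGS2:521;TARBP2:11	2.98	6.98	24.73	15.86	7.14
Endometrial Neoplasms	MESH:D016889	34	BIRC5:167;DCN:49;HOXA11:22;PTEN:100;SUZ12:13	2.37	5.62	29.24	17.79	6.07
Cleft Lip	MESH:D002971	28	FGFR1:73;FGFR2:90;FGFR3:60;SPRY2:19;TYMS:113	2.75	6.46	28.09	17.28	5.83
Leukemia, Promyelocytic, Acute	MESH:D015473	34	AKT1:315;CD44:70;CEBPA:78;ITGB2:46;RARA:81	2.37	5.62	26.32	15.97	5.81
Dermatitis, Atopic	MESH:D003876	37	CXCL10:87;IFNG:347;IL1B:492;IL4:228;TSLP:18	2.21	5.27	24.37	14.82	5.44
Neuroblastoma	MESH:D009447	39	IFNB1:48;MET:61;MYC:253;MYCN:31;NTRK2:37	2.11	5.05	28.09	16.57	5.26
Glioblastoma	MESH:D005909	42	IL1B:492;MMP2:194;NCOR1:39;TGM2:75;VEGFA:271	1.97	4.76	24.17	14.46	4.94
Cardiovascular Diseases	MESH:D002318	43	CBS:24;CCL2:283;EDN1:186;GH1:70;VCAM1:123	1.93	4.67	25.86	15.27	4.86
Liver Cirrhosis	MESH:D00103	49	CTGF:77;FGFR2:90;MMP2:194;SPP1:113;THBS1:68	1.7	4.18	25.9	15.04	4.38
Colitis, Ulcerative	MESH:D003093	50	GNA12:18;IL12B:194;IL1B:492;PTPN2:18;STAT3:127	1.67	4.11	26.77	15.44	4.32
Cell Transformation, Neoplastic	MESH:D002471	60	NOS2:456;SLC16A1:73;SLC2A1:88;TSC22D1:46;WNT5A:38	1.37	3.48	26.52	15.0	3.7
Lupus Erythematosus, Systemic	MESH:D008180	62	CLU:115;ETS1:35;FASLG:72;IL12B:194;IL4:228	1.32	3.38	25.71	14.55	3.58
Kidney Diseases	MESH:D007674	71	CDKN1A:375;HOXA11:22;LCN2:64;LRP2:19;TERT:80	1.11	2.97	28.15	15.56	3.2
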