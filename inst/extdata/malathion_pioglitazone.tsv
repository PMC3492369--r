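chemical	chemical_degree	disease	disease_degree	m	gene_degrees	c_xy_ref	p1_ref	p2_ref	s_ref	w_ref	geom_mean_ref
malathion	54	Breast Neoplasms	443	9	CENPF:29;CYP3A4:414;HRAS:95;HRAS1:42;IFNB1:48;IFNG:347;SOD2:191;TP53:458;TYMS:113	7.49	17.30	40.32	28.81	17.31	125.8
pioglitazone	60	Breast Neoplasms	443	9	CDKN1B:167;CYP3A4:414;IFNG:347;IL1B:492;NOS2:456;PTGS2:521;RB1:209;RELA:368;TNF:835	7.24	16.72	32.10	24.46	16.73	383.6
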