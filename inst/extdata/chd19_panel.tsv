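# 19-SNP CHD gene-score panel: rsID/gene/chromosome/RAF from a published healthy-UK-men
# sample; allele codes compiled from public dbSNP annotations (illustrative); per-allele
# weights are a required user input and ship as NA (see placeholderWeights() for a
# synthetic demonstration set).
rsid	gene	chromosome	risk_allele	other_allele	raf	weight	model
rs11591147	PCSK9	1	G	T	0.99	NA	additive
rs17465637	MIA3	1	C	A	0.71	NA	additive
rs646776	SORT1	1	T	C	0.78	NA	additive
rs1042031	APOB	2	A	G	0.18	NA	additive
rs9818870	MRAS	3	T	C	0.16	NA	additive
rs3798220	LPA	6	C	T	0.02	NA	additive
rs10455872	LPA	6	G	A	0.07	NA	additive
rs1799983	NOS3	7	T	G	0.33	NA	recessive
rs328	LPL	8	C	G	0.90	NA	additive
rs1801177	LPL	8	A	G	0.01	NA	additive
rs7025486	DAB2IP	9	A	G	0.26	NA	additive
rs10757274	9p21	9	G	A	0.48	NA	additive
rs1746048	CXCL12	10	C	T	0.86	NA	additive
rs662799	APOA5	11	G	A	0.06	NA	additive
rs17228212	SMAD3	15	C	T	0.31	NA	additive
rs708272	CETP	16	G	A	0.56	NA	additive
rs4341	ACE	17	C	G	0.52	NA	additive
rs7412	APOE	19	C	T	0.91	NA	additive
rs429358	APOE	19	C	T	0.17	NA	additive
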