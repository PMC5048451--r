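# Published validation of a 19-SNP cardiac risk genotyping array against previously
# determined genotypes: per-SNP number of pairwise-complete comparisons, discordant
# calls, and the reference-source genotype distribution (common homozygote /
# heterozygote / rare homozygote), transcribed verbatim from the published table.
# Note: the rs708272 genotype counts sum to 147, not its n_compared of 158 — an
# inconsistency present in the published table that is reproduced, not corrected.
rsid	n_compared	n_discordant	hom_common	het	hom_rare
rs11591147	144	0	139	5	0
rs17465637	158	2	84	68	6
rs646776	172	0	95	69	8
rs1042031	173	1	105	62	6
rs9818870	165	0	116	44	5
rs3798220	173	0	166	7	0
rs10455872	156	0	135	20	1
rs1799983	171	0	68	79	24
rs328	167	1	131	34	2
rs1801177	167	0	162	5	0
rs7025486	173	0	94	69	10
rs10757274	174	0	57	84	33
rs1746048	174	0	129	41	4
rs662799	148	0	133	13	2
rs17228212	173	0	83	72	18
rs708272	158	1	50	71	26
rs4341	168	0	47	81	40
rs7412	172	1	131	36	5
rs429358	172	0	139	32	1
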