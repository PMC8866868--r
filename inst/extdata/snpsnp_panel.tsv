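# 15-locus SNP-SNP microhaplotype panel: ARMS-PCR / SBE amplicon geometry,
# per-primer limit of detection (ng) and CE-observed SBE product size (bp).
# SNP1/SNP2 allele labels are placeholders consistent with the published
# mixture genotypes where those were printed (MH3, MH8, MH9, MH10, MH11,
# MH12, MH13) and synthetic elsewhere; rs-identifiers are not carried.
# Observed sizes for MH1-F2, MH12-F1, MH13-F2 and MH14-F1 were not printed
# and reuse the sibling primer's value (synthetic placeholders).
locus_id	snp1_alleles	snp2_alleles	arms_amplicon_bp	sbe_amplicon_bp	f1_target	f1_lod_ng	f1_observed_bp	f2_target	f2_lod_ng	f2_observed_bp
MH1	A/G	C/T	134	26	A	0.025	34	G	0.025	34
MH2	C/T	A/G	108	32	C	0.05	41	T	0.025	41
MH3	T/C	C/T	121	36	T	0.025	42	C	0.025	41
MH4	A/C	G/T	101	43	A	0.025	46	C	0.05	46
MH5	G/T	A/C	60	52	G	0.025	56	T	0.025	56
MH6	A/T	C/G	114	61	A	0.025	64	T	0.025	64
MH7	C/G	A/T	90	65	C	0.05	67	G	0.025	67
MH8	A/C	G/A	126	71	A	0.025	77	C	0.025	77
MH9	C/T	A/G	150	27	C	0.025	35	T	0.05	33
MH10	C/G	T/A	106	31	C	0.025	39	G	0.05	38
MH11	C/T	A/G	69	35	C	0.025	43	T	0.05	42
MH12	C/T	G/A	141	39	C	0.025	44	T	0.05	44
MH13	C/T	G/A	95	43	C	0.05	48	T	0.05	48
MH14	G/A	T/C	79	58	G	0.025	61	A	0.05	61
MH15	A/G	C/T	113	63	A	0.025	68	G	0.025	68
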