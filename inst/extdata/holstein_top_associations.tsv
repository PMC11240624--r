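chrom	position	gene_id	gene_name	trait	rank	p	F	reported_tier
7	17361304	LOC100337044	Adhesion G protein-coupled receptor E3	PL	1	5.99e-5	17.05	significant
14	1600535	LOC112449566	Cytochrome P450 11B1, mitochondrial-like	PL	2	1.01e-4	15.96	significant
15	47227535	OR52E6	Olfactory receptor family 52 subfamily E member 6	MET	1	2.10e-6	24.34	significant
15	47227535	OR52E6	Olfactory receptor family 52 subfamily E member 6	FAT	1	8.66e-6	21.21	significant
15	47245425	OR52N2	Olfactory receptor family 52 subfamily N member 2	MLK	1	4.41e-6	22.69	significant
15	47245425	OR52N2	Olfactory receptor family 52 subfamily N member 2	PRO	1	1.38e-5	20.20	significant
3	54809083	LOC785445	Heterogeneous nuclear ribonucleoprotein A1-like	DCE	1	1.90e-4	14.63	suggestive
10	22785310	LOC100296997	T cell receptor alpha variable 14/delta variable 4-like	LIV	1	1.61e-4	14.97	suggestive
14	1600535	LOC112449566	Cytochrome P450 11B1, mitochondrial-like	FUA	1	1.60e-4	14.99	suggestive
15	47227535	OR52E6	Olfactory receptor family 52 subfamily E member 6	HTH	1	1.05e-4	15.86	suggestive
15	47227535	OR52E6	Olfactory receptor family 52 subfamily E member 6	EFC	1	1.67e-4	14.91	suggestive
15	47245425	OR52N2	Olfactory receptor family 52 subfamily N member 2	MET	2	1.12e-4	15.73	suggestive
15	49043281	LOC785207	Olfactory receptor family 52 subfamily S member 2	FS	1	1.33e-4	15.38	suggestive
18	57253674	LOC112442406	Zinc finger protein 85-like	KET	1	1.61e-4	14.98	suggestive
19	41468220	LOC112442670	Keratin-associated protein 9-7-like	MFV	1	1.12e-4	15.74	suggestive
20	6875546	LOC104975198	Uncharacterized	CCR	1	1.85e-4	14.69	suggestive
27	6023993	LOC789175	beta-defensin 103B-like	FLC	1	1.52e-4	15.10	suggestive
29	27350311	LOC782221	Olfactory receptor family 8 subfamily B member 1AQ	CT	1	2.01e-4	14.52	suggestive
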