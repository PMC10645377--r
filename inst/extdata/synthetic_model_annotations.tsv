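model_id	phenotype	b7h3_level	b7h3_positive	RB1	TP53	ATR	CHD1	BRCA2	slfn11	repstress_z	rb1_score_z	nauc_median	observed_response
N01	SCNPC	5.7	TRUE	biallelic_loss	altered	wt	wt	wt	TRUE	2.1	1.9	0.22	R
N02	SCNPC	5.5	TRUE	biallelic_loss	altered	wt	wt	wt	TRUE	1.9	1.7	0.25	R
N03	SCNPC	5.9	TRUE	biallelic_loss	altered	wt	wt	wt	TRUE	1.7	1.6	0.3	R
N04	SCNPC	5.4	TRUE	biallelic_loss	altered	wt	wt	wt	FALSE	1.6	1.5	0.35	R
N05	SCNPC	5.6	TRUE	biallelic_loss	altered	wt	wt	wt	FALSE	1.4	1.3	0.4	R
N06	DNPC	5.8	TRUE	biallelic_loss	altered	wt	wt	wt	TRUE	1.8	1.6	0.28	R
N07	DNPC	5.3	TRUE	biallelic_loss	altered	wt	wt	wt	FALSE	1.3	1.2	0.45	R
A01	ARPC	5.6	TRUE	biallelic_loss	altered	wt	wt	wt	TRUE	1.6	1.4	0.35	R
A02	ARPC	5.5	TRUE	biallelic_loss	altered	wt	wt	wt	TRUE	1.5	1.3	0.4	R
A03	ARPC	7.8	TRUE	wt	altered	wt	wt	wt	TRUE	1.3	0.4	0.35	R
A04	ARPC	7.5	TRUE	wt	altered	wt	wt	wt	TRUE	1.2	0.3	0.4	R
A05	ARPC	7.2	TRUE	wt	altered	wt	wt	wt	TRUE	0.5	0.1	0.45	R
A06	ARPC	7	TRUE	wt	altered	wt	wt	wt	TRUE	0.3	0	0.5	R
A07	ARPC	5.7	TRUE	monoallelic_or_wt	altered	wt	wt	wt	TRUE	0.2	-0.1	0.55	R
A08	ARPC	5.6	TRUE	wt	wt	wt	wt	wt	TRUE	0.1	-0.2	0.6	R
A09	ARPC	5.8	TRUE	wt	altered	wt	altered	wt	FALSE	0	-0.3	0.45	R
A10	ARPC	5.9	TRUE	wt	wt	wt	altered	wt	FALSE	-0.1	-0.4	0.5	R
A11	ARPC	5.5	TRUE	wt	wt	altered	wt	wt	FALSE	-0.2	-0.5	0.55	R
A12	ARPC	5.7	TRUE	wt	wt	wt	wt	wt	FALSE	-0.5	-0.7	0.85	NR
A13	ARPC	5.6	TRUE	wt	wt	wt	wt	altered	FALSE	-0.6	-0.8	0.9	NR
A14	ARPC	5.8	TRUE	wt	monoallelic_or_wt	wt	wt	wt	FALSE	-0.7	-0.9	0.95	NR
A15	ARPC	5.5	TRUE	monoallelic_or_wt	wt	wt	wt	wt	FALSE	-0.8	-1	1	NR
A16	ARPC	5.4	TRUE	wt	wt	wt	wt	wt	FALSE	-0.9	-1.1	0.9	NR
A17	ARPC	5.6	TRUE	wt	monoallelic_or_wt	wt	wt	wt	FALSE	-1	-1.2	0.95	NR
A18	ARPC	5.9	TRUE	wt	wt	wt	wt	wt	FALSE	-1.1	-1.3	0.85	NR
A19	ARPC	5.5	TRUE	wt	altered	wt	wt	wt	FALSE	-0.4	-0.6	0.8	NR
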