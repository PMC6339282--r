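##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	A3H001	A3H002	A3H003	A3H004	A3H005	A3H006	A3H007	A3H008	A3H009	A3H010	A3H011	A3H012
A3H	43	N15del	AAC	-	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
A3H	53	R18L	G	T	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
A3H	313	G105R	G	C	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
A3H	361	K121E	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
A3H	418	K140E	A	G	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
A3H	534	E178D	G	C	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
A3H	129	T43T	G	C	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/1	0/1	0/1
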