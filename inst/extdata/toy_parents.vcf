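##fileformat=VCFv4.2
##contig=<ID=2L,length=1000000>
##contig=<ID=X,length=1000000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P1	P2	C
2L	100	.	A	T	60	PASS	.	GT	1/1	0/0	1/1
2L	200	.	C	G	60	PASS	.	GT	1/1	0/0	0/0
2L	300	.	G	A	60	PASS	.	GT	0/1	0/0	0/0
2L	350	.	GT	G	60	PASS	.	GT	1/1	0/0	0/0
X	100	.	T	C	60	PASS	.	GT	1/1	0/0	1/1
X	200	.	A	G	60	PASS	.	GT	1/1	0/0	0/0
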