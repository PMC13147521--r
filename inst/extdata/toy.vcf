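##fileformat=VCFv4.2
##contig=<ID=2L,length=1000000>
##contig=<ID=X,length=1000000>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total Depth">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	m1	m2
2L	100	.	A	T	60	PASS	DP=40	GT:AD	0/1:10,10	0/0:20,0
2L	200	.	C	G	60	PASS	DP=40	GT:AD	0/1:15,5	0/1:30,10
2L	300	.	G	A	60	PASS	DP=14	GT:AD	0/1:4,3	0/0:6,2
2L	350	.	GT	G	60	PASS	DP=20	GT:AD	0/1:5,5	0/0:10,0
X	100	.	T	C	60	PASS	DP=30	GT:AD	0/1:8,8	0/0:12,0
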