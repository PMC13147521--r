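sample	chrom	pos	ref_count	alt_count
s1	2L	100	10	10
s1	2L	200	15	5
s1	2L	300	4	3
s1	2L	400	20	0
s2	2L	100	20	0
s2	2L	200	30	10
s2	2L	300	6	2
s2	2L	400	18	0
s3	2L	100	12	12
s3	2L	200	12	4
s3	2L	300	9	3
s3	2L	400	25	0
s4	2L	100	16	0
s4	2L	200	24	8
s4	2L	300	3	4
s4	2L	400	30	0
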