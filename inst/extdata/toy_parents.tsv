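stock	chrom	pos	gt	is_indel
P1	2L	100	hom_alt	FALSE
P1	2L	200	hom_alt	FALSE
P1	2L	300	het	FALSE
P1	2L	400	hom_alt	FALSE
P1	2L	500	hom_alt	TRUE
P1	X	100	hom_alt	FALSE
P1	X	200	hom_alt	FALSE
P1	3L	100	hom_alt	FALSE
P2	2L	100	hom_ref	FALSE
P2	2L	200	hom_ref	FALSE
P2	2L	300	hom_ref	FALSE
P2	2L	400	hom_alt	FALSE
P2	2L	500	hom_ref	FALSE
P2	X	100	hom_ref	FALSE
P2	X	200	hom_ref	FALSE
P2	3L	100	hom_ref	FALSE
C	2L	100	hom_alt	FALSE
C	X	100	hom_alt	FALSE
C	X	200	hom_ref	FALSE
C	3L	100	het	FALSE
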