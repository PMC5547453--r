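##fileformat=VCFv4.2
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
20	14370	rs6054257	G	A	29	PASS	.
20	17330	.	T	A	3	q10	.
20	1110696	rs6040355	A	G,T	67	PASS	.
20	1230237	.	T	.	47	PASS	.
20	1234567	microsat1	GTC	G,GTCT	50	PASS	.
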