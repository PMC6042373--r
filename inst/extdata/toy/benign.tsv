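chrom	pos	ref	alt
1	2000	A	G
1	2010	A	G
1	1000	A	G
1	1010	A	G
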