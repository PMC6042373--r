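chrom	pos	ref	alt
1	1000	A	G
1	1010	A	G
1	1020	A	G
1	1030	A	G
1	1040	A	G
1	1050	A	G
1	1060	A	G
1	1070	A	G
1	1080	A	G
1	1090	A	G
1	1100	A	G
1	1110	A	G
1	1020	A	G
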