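chrom	pos	ref	alt	pvalue
1	3000	A	G	1e-09
1	3010	A	G	1e-09
1	3020	A	G	1e-07
1	3030	A	G	1e-10
1	3040	A	G	1e-09
1	3050	A	G	5e-01
1	3060	A	G	1e-12
1	3070	A	G	1e-09
1	3080	A	G	1e-09
1	3090	A	G	1e-11
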