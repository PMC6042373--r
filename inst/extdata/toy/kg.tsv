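chrom	pos	ref	alt
1	5000	A	G
1	5010	A	G
1	5020	A	G
1	5030	A	G
1	5040	A	G
1	5050	A	G
1	5060	A	G
1	5070	A	G
1	5080	A	G
1	5090	A	G
1	5100	A	G
1	5110	A	G
1	5120	A	G
1	5130	A	G
1	5140	A	G
1	5150	A	G
1	5160	A	G
1	5170	A	G
1	5180	A	G
1	5190	A	G
1	6000	A	G
1	6010	A	G
1	6020	A	G
1	6030	A	G
1	6040	A	G
1	6050	A	G
1	6060	A	G
1	6070	A	G
1	6080	A	G
1	6090	A	G
1	6100	A	G
1	6110	A	G
1	6120	A	G
1	6130	A	G
1	6140	A	G
1	6150	A	G
1	6160	A	G
1	6170	A	G
1	6180	A	G
1	6190	A	G
1	7000	A	G
1	7010	A	G
1	7020	A	G
1	3000	A	G
1	3010	A	G
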