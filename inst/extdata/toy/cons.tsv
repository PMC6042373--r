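chrom	pos	score
1	3000	0.9
1	3010	0.9
1	3020	0.9
1	3030	0.9
1	3040	0.9
1	3050	0.9
1	3060	0.9
1	3070	0.9
1	3080	0.9
1	3090	0.9
1	5000	0.85
1	5010	0.85
1	5020	0.85
1	5030	0.85
1	5040	0.85
1	5050	0.85
1	5060	0.85
1	5070	0.85
1	5080	0.85
1	5090	0.85
1	5100	0.85
1	5110	0.85
1	5120	0.85
1	5130	0.85
1	5140	0.85
1	5150	0.85
1	5160	0.85
1	5170	0.85
1	5180	0.85
1	5190	0.85
1	6000	0.05
1	6010	0.05
1	6020	0.05
1	6030	0.05
1	6040	0.05
1	6050	0.05
1	6060	0.05
1	6070	0.05
1	6080	0.05
1	6090	0.05
1	6100	0.05
1	6110	0.05
1	6120	0.05
1	6130	0.05
1	6140	0.05
1	6150	0.05
1	6160	0.05
1	6170	0.05
1	6180	0.05
1	6190	0.05
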