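chrom	pos	p_EUR	p_EAS	n_EUR	n_EAS
1	5000	0.5	0.5	100	100
1	5010	0.5	0.5	100	100
1	5020	0.5	0.5	100	100
1	5030	0.5	0.5	100	100
1	5040	0.5	0.5	100	100
1	5050	0.5	0.5	100	100
1	5060	0.5	0.5	100	100
1	5070	0.5	0.5	100	100
1	5080	0.5	0.5	100	100
1	5090	0.5	0.5	100	100
1	5100	0.5	0.5	100	100
1	5110	0.5	0.5	100	100
1	5120	0.5	0.5	100	100
1	5130	0.5	0.5	100	100
1	5140	0.5	0.5	100	100
1	5150	0.5	0.5	100	100
1	5160	0.5	0.5	100	100
1	5170	0.5	0.5	100	100
1	5180	0.5	0.5	100	100
1	5190	0.5	0.5	100	100
1	6000	0.5	0.5	100	100
1	6010	0.5	0.5	100	100
1	6020	0.5	0.5	100	100
1	6030	0.5	0.5	100	100
1	6040	0.5	0.5	100	100
1	6050	0.5	0.5	100	100
1	6060	0.5	0.5	100	100
1	6070	0.5	0.5	100	100
1	6080	0.5	0.5	100	100
1	6090	0.5	0.5	100	100
1	6100	0.5	0.5	100	100
1	6110	0.5	0.5	100	100
1	6120	0.5	0.5	100	100
1	6130	0.5	0.5	100	100
1	6140	0.5	0.5	100	100
1	6150	0.5	0.5	100	100
1	6160	0.5	0.5	100	100
1	6170	0.5	0.5	100	100
1	6180	0.5	0.5	100	100
1	6190	0.5	0.5	100	100
1	7000	0.05	0.95	100	100
1	7010	0.05	0.95	100	100
1	7020	0.05	0.95	100	100
1	3000	0.5	0.5	100	100
1	3010	0.5	0.5	100	100
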