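1	2999	3000	enh
1	3009	3010	enh
1	3019	3020	enh
1	3039	3040	enh
1	3049	3050	enh
1	3059	3060	enh
1	3079	3080	enh
1	3089	3090	enh
1	4999	5000	enh
1	5009	5010	enh
1	5019	5020	enh
1	5029	5030	enh
1	5039	5040	enh
1	5049	5050	enh
1	5059	5060	enh
1	5069	5070	enh
1	5079	5080	enh
1	5089	5090	enh
1	5099	5100	enh
1	5109	5110	enh
1	5119	5120	enh
1	5129	5130	enh
1	5139	5140	enh
1	5149	5150	enh
1	5159	5160	enh
1	5169	5170	enh
1	5179	5180	enh
1	5189	5190	enh
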