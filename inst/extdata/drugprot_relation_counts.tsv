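type	train_count	train_pct	dev_count	dev_pct
INHIBITOR	5392	31.3	1152	30.6
DIRECT-REGULATOR	2250	13.0	458	12.2
SUBSTRATE	2003	11.6	495	13.2
ACTIVATOR	1429	8.3	246	6.5
INDIRECT-UPREGULATOR	1379	8.0	302	8.0
INDIRECT-DOWNREGULATOR	1330	7.7	332	8.8
ANTAGONIST	972	5.6	218	5.8
PRODUCT-OF	921	5.3	158	4.2
PART-OF	886	5.1	258	6.9
AGONIST	659	3.8	131	3.5
AGONIST-ACTIVATOR	29	0.2	10	0.3
SUBSTRATE_PRODUCT-OF	25	0.1	3	0.1
AGONIST-INHIBITOR	13	0.1	2	0.1
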