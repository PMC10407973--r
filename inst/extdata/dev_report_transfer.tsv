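type	precision	recall	f1
INDIRECT-DOWNREGULATOR	77.52	75.30	76.36
INDIRECT-UPREGULATOR	79.98	73.78	76.76
DIRECT-REGULATOR	71.12	61.36	65.86
ACTIVATOR	77.28	71.62	74.34
INHIBITOR	86.80	86.04	86.42
AGONIST	80.48	72.82	76.44
AGONIST-ACTIVATOR	100.00	48.00	64.78
AGONIST-INHIBITOR	66.70	100.00	80.00
ANTAGONIST	92.26	91.92	92.10
PRODUCT-OF	68.24	70.40	69.24
SUBSTRATE	71.02	76.58	73.70
SUBSTRATE_PRODUCT-OF	60.02	60.02	59.44
PART-OF	73.20	75.66	74.34
Micro-average	79.18	77.30	78.22
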