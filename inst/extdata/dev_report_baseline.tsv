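type	precision	recall	f1
INDIRECT-DOWNREGULATOR	75.56	75.72	75.64
INDIRECT-UPREGULATOR	80.84	74.26	77.30
DIRECT-REGULATOR	70.32	62.24	65.84
ACTIVATOR	76.24	72.76	74.32
INHIBITOR	84.58	86.64	85.58
AGONIST	82.12	72.22	76.80
AGONIST-ACTIVATOR	96.66	48.00	63.94
AGONIST-INHIBITOR	66.70	100.00	80.00
ANTAGONIST	93.02	90.36	91.64
PRODUCT-OF	63.42	69.76	66.26
SUBSTRATE	73.86	77.30	75.52
SUBSTRATE_PRODUCT-OF	66.70	66.70	66.70
PART-OF	71.60	77.60	74.38
Micro-average	78.22	77.86	78.04
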