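gene_id	array_r	qpcr_r	qpcr_p
APCDD1	-0.74	-0.51	0.03
CAMK2B	0.82	0.50	0.01
EIF3I	0.64	0.50	0.02
HGS	0.70	0.67	0.00
NUDC	0.65	0.72	0.00
POLRMT	0.60	0.51	0.02
TIE1	0.67	0.53	0.01
TSC2	0.69	0.47	0.03
SGK			
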