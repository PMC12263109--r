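gene	af	clinvar_class	spliceai
PAX6	0.0002	likely_pathogenic	0.12
PAX6	0.3	benign	.
SCN1A	0.004	vus	.
MECP2	0.05	unknown	0.93
TTN	0.2	vus	0.4
BRCA2	0.008	.	.
ACTB	0.01	unknown	0.8
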