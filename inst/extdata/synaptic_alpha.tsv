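pre	RS	IB	NRS	LTS	TC	RE
RS	0.05	0.05	0.1	0.5	NA	NA
IB	0.1	0.1	0.1	0.05	NA	NA
NRS	0.05	0.1	0.05	0.625	0.75	0.8
LTS	0.1	0.05	0.1	NA	NA	NA
TC	1	1	0.07	0.149	NA	0.94
RE	NA	NA	NA	NA	20	20
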