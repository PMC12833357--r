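pre	RS	IB	NRS	LTS	TC	RE
RS	0.15	0.05	0.01	0.2	NA	NA
IB	0.15	0.05	0.01	0.08	NA	NA
NRS	0.05	0.01	0.03	0.109	0.3	0.09
LTS	0.2	0.7	0.01	NA	NA	NA
TC	0.15	0.15	0.006	0.048	NA	0.18
RE	NA	NA	NA	NA	0.162	0.162
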