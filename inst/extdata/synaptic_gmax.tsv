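pre	receptor	RS	IB	NRS	LTS	TC	RE
RS	AMPA	0.3	0.7	0.3	0.1	NA	NA
IB	AMPA	1	0.3	0.05	0.08	NA	NA
NRS	AMPA	0.1	0.3	2	0.2	0.02	2.4
LTS	GABAA	0.09	0.1	0.75	NA	NA	NA
LTS	GABAB	0.03	0.03	0.03	NA	NA	NA
TC	AMPA	1	0.7	1.2	0.4	NA	0.2
RE	GABAA	NA	NA	NA	NA	0.02	0.2
RE	GABAB	NA	NA	NA	NA	0.04	NA
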