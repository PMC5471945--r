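drug_id	enzyme_label
allopurinol	XDH
azacitidine	DNMT1
capecitabine	TYMS
cladribine	POLA1,POLB
cladribine	RRM1
clofarabine	POLA1,POLB
clofarabine	RRM1
cytarabine	POLA1,POLB
decitabine	DNMT1
floxuridine	TYMS
fludarabine	POLA1,POLB
fludarabine	RRM1
gemcitabine	NME1/2
gemcitabine	RRM1
gemcitabine	TYMS
methotrexate	DHFR
nelarabine	POLA1,POLB
pemetrexed	ATIC
pemetrexed	DHFR
pemetrexed	GART
pemetrexed	TYMS
pralatrexate	DHFR
pralatrexate	TYMS
raltitrexed	TYMS
ribavirin	ENPP1
ribavirin	IMPDH1/2
trifluridine	TYMS
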