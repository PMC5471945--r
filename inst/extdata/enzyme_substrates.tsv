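label	ec_numbers	substrate_ids	excluded_cosubstrates
TYMS	2.1.1.45	dUMP;CH2THF	water
POLA1,POLB	2.7.7.7	dATP;dGTP;dCTP	water;diphosphate
DHFR	1.5.1.3	DHF;THF	water;NADPH
RRM1	1.17.4.1	ADP;CDP	water;thioredoxin
DNMT1	2.1.1.37	cytidine	water;S-adenosylmethionine
IMPDH1/2	1.1.1.205	IMP	water;NAD
ENPP1	3.6.1.9	dNAD	water
ATIC	2.1.2.3	f10THF	water
GART	2.1.2.2	f10THF	water
NME1/2	2.7.4.6	dCDP	water;ATP
XDH	1.17.3.2	hypoxanthine	water;NAD
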