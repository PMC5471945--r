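id	name	role	smiles
dUMP	dUMP	metabolite	O=C1NC(=O)C=CN1C1CC(O)C(COP(O)(O)=O)O1
CH2THF	5,10-Methylene-tetrahydrofolate	metabolite	Nc1nc2NCC3CN(c4ccc(cc4)C(=O)NC(CCC(O)=O)C(O)=O)CN3c2c(=O)[nH]1
dATP	dATP	metabolite	Nc1ncnc2n(cnc12)C1CC(O)C(COP(O)(=O)OP(O)(=O)OP(O)(O)=O)O1
dGTP	dGTP	metabolite	Nc1nc2n(cnc2c(=O)[nH]1)C1CC(O)C(COP(O)(=O)OP(O)(=O)OP(O)(O)=O)O1
dCTP	dCTP	metabolite	Nc1ccn(c(=O)n1)C1CC(O)C(COP(O)(=O)OP(O)(=O)OP(O)(O)=O)O1
DHF	7,8-Dihydrofolate	metabolite	Nc1nc2NCC(CNc3ccc(cc3)C(=O)NC(CCC(O)=O)C(O)=O)=Nc2c(=O)[nH]1
THF	(6S)-5,6,7,8-Tetrahydrofolate	metabolite	Nc1nc2NCC(CNc3ccc(cc3)C(=O)NC(CCC(O)=O)C(O)=O)Nc2c(=O)[nH]1
ADP	ADP	metabolite	Nc1ncnc2n(cnc12)C1OC(COP(O)(=O)OP(O)(O)=O)C(O)C1O
CDP	CDP	metabolite	Nc1ccn(c(=O)n1)C1OC(COP(O)(=O)OP(O)(O)=O)C(O)C1O
cytidine	Cytidine	metabolite	Nc1ccn(c(=O)n1)C1OC(CO)C(O)C1O
IMP	IMP	metabolite	O=c1[nH]cnc2n(cnc12)C1OC(COP(O)(O)=O)C(O)C1O
dNAD	Deamino-NAD+	metabolite	OC(=O)c1ccc[n+](c1)C1OC(COP(O)(=O)OP([O-])(=O)OCC2OC(n3cnc4c(N)ncnc34)C(O)C2O)C(O)C1O
f10THF	10-Formyl-tetrahydrofolate	metabolite	Nc1nc2NCC(CN(C=O)c3ccc(cc3)C(=O)NC(CCC(O)=O)C(O)=O)Nc2c(=O)[nH]1
dCDP	dCDP	metabolite	Nc1ccn(c(=O)n1)C1CC(O)C(COP(O)(=O)OP(O)(O)=O)O1
hypoxanthine	Hypoxanthine	metabolite	O=c1[nH]cnc2[nH]cnc12
trifluridine	Trifluridine	drug	OCC1OC(CC1O)n1cc(C(F)(F)F)c(=O)[nH]c1=O
floxuridine	Floxuridine	drug	OCC1OC(CC1O)n1cc(F)c(=O)[nH]c1=O
gemcitabine	Gemcitabine	drug	Nc1ccn(c(=O)n1)C1OC(CO)C(O)C1(F)F
capecitabine	Capecitabine	drug	CCCCCOC(=O)Nc1nc(=O)n(cc1F)C1OC(C)C(O)C1O
pemetrexed	Pemetrexed	drug	Nc1nc2[nH]cc(CCc3ccc(cc3)C(=O)NC(CCC(O)=O)C(O)=O)c2c(=O)[nH]1
raltitrexed	Raltitrexed	drug	Cc1nc2ccc(CN(C)c3ccc(s3)C(=O)NC(CCC(O)=O)C(O)=O)cc2c(=O)[nH]1
pralatrexate	Pralatrexate	drug	C#CCC(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(cc1)C(=O)NC(CCC(O)=O)C(O)=O
cladribine	Cladribine	drug	Nc1nc(Cl)nc2n(cnc12)C1CC(O)C(CO)O1
clofarabine	Clofarabine	drug	Nc1nc(Cl)nc2n(cnc12)C1OC(CO)C(O)C1F
fludarabine	Fludarabine	drug	Nc1nc(F)nc2n(cnc12)C1OC(CO)C(O)C1O
nelarabine	Nelarabine	drug	COc1nc(N)nc2n(cnc12)C1OC(CO)C(O)C1O
cytarabine	Cytarabine	drug	Nc1ccn(c(=O)n1)C1OC(CO)C(O)C1O
methotrexate	Methotrexate	drug	CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(cc1)C(=O)NC(CCC(O)=O)C(O)=O
azacitidine	Azacitidine	drug	Nc1ncn(c(=O)n1)C1OC(CO)C(O)C1O
decitabine	Decitabine	drug	Nc1ncn(c(=O)n1)C1CC(O)C(CO)O1
ribavirin	Ribavirin	drug	NC(=O)c1ncn(n1)C1OC(CO)C(O)C1O
allopurinol	Allopurinol	drug	O=c1[nH]cnc2[nH]ncc12
levoleucovorin	Levoleucovorin	drug	Nc1nc2NCC(CNc3ccc(cc3)C(=O)NC(CCC(O)=O)C(O)=O)N(C=O)c2c(=O)[nH]1
vidarabine	Vidarabine	drug	Nc1ncnc2n(cnc12)C1OC(CO)C(O)C1O
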