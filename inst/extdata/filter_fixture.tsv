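smiles	kind	keep
c1ccccc1	RF	1
C1CC1	RF	1
C1CCCCCC1	RF	1
C1CCCCCCC1	RF	0
c1ccc2ccccc2c1	RF	1
c1ccc2cc3ccccc3cc2c1	RF	0
Cc1ccccc1	RF	1
CCCCc1ccccc1	RF	0
CN1CCOCC1	RF	1
O=C1CCCCC1	RF	1
c1ccncc1	RF	1
c1cnc2[nH]ccc2c1	RF	1
OC1CCC(O)C(O)C1	RF	1
OC1CC(O)C(O)C1O	RF	0
C1CC2CCC1CC2	RF	1
C1CC2(C1)CCCCC2	RF	1
C12CC3CC(C1)CC(C2)C3	RF	0
NC1CCNCC1N	RF	1
OCC1CCCCC1CO	RF	0
N#CC1CC1C#N	RF	0
C1CC2(C1)CCC21CC1	RF	0
c1ccc(-c2ccccc2)cc1	RF	1
C1CCOC1	RF	1
O=S1(=O)CCCC1	RF	1
Clc1ccc(Cl)c(Cl)c1Cl	RF	0
C	AF	1
CC	AF	1
CCC	AF	1
CC(C)C	AF	1
CC(C)(C)C	AF	0
C#N	AF	1
C#CC#N	AF	0
NCCO	AF	1
OCC(O)CO	AF	1
FC(F)F	AF	1
FC(F)(F)F	AF	0
CCOCCOCC	AF	1
OCCOCCOCCO	AF	1
OCCOCCOCCOCCO	AF	0
NCCN(CCN)CCN	AF	1
CC(C)C(C)C	AF	1
CC(C)C(C)(C)C	AF	0
C=O	AF	1
C=C	AF	1
C#C	AF	1
CC#CC	AF	1
FC(Cl)Br	AF	1
N#CCC#N	AF	0
CC(C)(C)CC	AF	0
CC(N)C(=O)O	AF	1
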