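CC(=O)Oc1ccccc1C(=O)O
CC(C)Cc1ccc(cc1)C(C)C(=O)O
CC(C)Cc1ccc(cc1)[C@@H](C)C(=O)O
CC(C)Cc1ccc(cc1)[C@H](C)C(=O)O
CN1C=NC2=C1C(=O)N(C(=O)N2C)C
Clc1ccccc1C2=NCC(=O)Nc3ccc(cc23)N(=O)=O
CC(N)Cc1ccccc1
C[C@H](N)Cc1ccccc1
C[C@@H](N)Cc1ccccc1
NC(=O)c1ccc[nH]1
CCO
CCN(CC)CC
c1ccccc1
c1ccc2ccccc2c1
OC(=O)c1ccccc1O
CC(=O)Nc1ccc(O)cc1
Oc1ccc(cc1)C(c2ccc(O)cc2)C
NCCc1ccc(O)c(O)c1
OCC(O)CO
CC(C)NCC(O)COc1ccc(COCCOC(C)C)cc1
CC(C)NCC(O)COc1ccccc1CC=C
COc1ccc2cc(ccc2c1)C(C)C(=O)O
COc1ccc2cc(ccc2c1)[C@@H](C)C(=O)O
CN(C)CCCN1c2ccccc2Sc3ccc(Cl)cc13
CN(C)CCCN1c2ccccc2CCc3ccccc13
OC(=O)CCc1ccccc1
NC(Cc1ccccc1)C(=O)O
N[C@@H](Cc1ccccc1)C(=O)O
N[C@H](Cc1ccccc1)C(=O)O
OC(=O)C(N)CC(=O)O
CSCCC(N)C(=O)O
CC(C)C(N)C(=O)O
CC(O)C(N)C(=O)O
NC(CO)C(=O)O
NC(CS)C(=O)O
NCCCCC(N)C(=O)O
NC(CCC(=O)O)C(=O)O
OC(=O)c1cc(O)c(O)c(O)c1
Oc1ccccc1
Oc1ccc(Cl)cc1
Nc1ccc(cc1)S(=O)(=O)N
CC(=O)NS(=O)(=O)c1ccc(N)cc1
Clc1ccc(cc1)C(c2ccccc2)N3CCN(CCOCCO)CC3
CN1CCC[C@H]1c2cccnc2
CN1CCC[C@@H]1c2cccnc2
CN1CCCC1c2cccnc2
COC(=O)C1=C(C)NC(=C(C1c2ccccc2N(=O)=O)C(=O)OC)C
CCOC(=O)C1=C(COCCN)NC(=C(C1c2ccccc2Cl)C(=O)OC)C
CC(CS)C(=O)N1CCCC1C(=O)O
CC(CS)C(=O)N1CCC[C@H]1C(=O)O
OC(=O)C1CCCN1
O=C1CCCCCN1
OCCN1CCN(CCCN2c3ccccc3Sc4ccc(Cl)cc24)CC1
Fc1ccc(cc1)C(O)CCCN2CCC(CC2)C(O)(c3ccccc3)c4ccccc4
CC1=CC(=O)C=CC1=O
O=C(O)c1ccccc1C(=O)O
OCC1OC(O)C(O)C(O)C1O
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O
CC(=O)OCC1OC(OC(=O)C)C(OC(=O)C)C(OC(=O)C)C1OC(=O)C
Nc1ncnc2n(cnc12)C3OC(CO)C(O)C3O
Cn1cnc2c1c(=O)n(C)c(=O)n2C
O=c1[nH]c(=O)c2[nH]cnc2[nH]1
Nc1nc2[nH]cnc2c(=O)[nH]1
CC12CCC3C(CCc4cc(O)ccc34)C1CCC2O
C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1CC[C@@H]2O
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
CC(C)(C)NC[C@H](O)c1ccc(O)c(CO)c1
CNC[C@H](O)c1ccc(O)c(O)c1
CNCC(O)c1ccc(O)c(O)c1
CC(C)NCC(O)c1ccc(O)c(O)c1
OCC(O)COC(=O)c1ccccc1Nc2cccc(c2)C(F)(F)F
CCCCc1oc2ccccc2c1C(=O)c3cc(I)c(OCCN(CC)CC)c(I)c3
CCCC(=O)Nc1ccc(OCC(O)CNC(C)C)c(c1)C(C)=O
CC(=O)c1ccc2Sc3ccccc3N(CCCN4CCN(C)CC4)c2c1
COc1cc2c(cc1OC)C(=O)C(CC2)Cc3ccN4CCc5cc(OC)c(OC)cc5C34
CCN(CC)C(=O)c1ccc(N)cc1
NC(=O)N1c2ccccc2C=Cc3ccccc13
Clc1ccccc1c2nc3ccccc3n2Cc4ccc(cc4)c5ccccc5c6nnn[nH]6
CC(C)(C)c1ccc(cc1)C(O)CCCN2CCC(CC2)C(O)(c3ccccc3)c4ccccc4
O=C(Nc1ccccc1)c2ccccc2
CN(C)c1ccc(cc1)C(=O)O
CCOC(=O)c1ccc(N)cc1
Cc1ccccc1N
Clc1ccc(Cl)cc1
Oc1ccc2[nH]cc(CCN)c2c1
NCCc1c[nH]c2ccccc12
COc1ccc2[nH]cc(CCNC(C)=O)c2c1
CN(C)CCc1c[nH]c2ccccc12
OC(=O)Cc1c[nH]c2ccccc12
Fc1ccc2c(c1)onc2C3CCN(CCc4c(C)nc5ccccn45)CC3
CC(=O)OC1CC2CCC3C(CCC4(C)C3CCC4(O)C#C)C2(C)C1
COc1ccc(cc1)CCN2CCC(CC2)Nc3nc4ccccc4n3Cc5ccc(F)cc5
OC(c1ccccc1)(c2ccccc2)C3CCN(CC3)CCc4ccccc4
CC(C)(C)NCC(O)COc1cccc2[nH]ccc12
CC(C)NCC(O)COc1cccc2ccccc12
CC(C)NC[C@@H](O)COc1cccc2ccccc12
COCCc1ccc(OCC(O)CNC(C)C)cc1
CCOc1ccccc1OCCNC(C)Cc2ccc3OCOc3c2
Cc1oc2ccccc2c1C(=O)c3ccc(O)cc3
CC(C)(Oc1ccc(cc1)CCNC(=O)c2ccc(Cl)cc2)C(=O)O
CN1CCN(CC1)C2=Nc3ccccc3Oc4ccc(Cl)cc24
ClC1=CC2=C(C=C1)N=C(C3=CC=CC=C3)CC(=O)N2
O=C1CC2(CCCC2)CC(=O)N1CCCCN3CCN(CC3)c4ncccn4
COc1ccccc1N2CCN(CCCCOc3ccc4CCC(=O)Nc4c3)CC2
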