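# Synthetic stand-in inhibitor panel: known aromatase-inhibitor
# chemotypes plus invented azole structures; NOT the assayed study set.
N#Cc1ccc(C(c2ccc(C#N)cc2)n2cncn2)cc1	1	letrozole
CC(C)(C#N)c1cc(Cn2cncn2)cc(C(C)(C)C#N)c1	2	anastrozole
Cn1nnc2cc(C(c3ccc(Cl)cc3)n3cncn3)ccc21	3	vorozole
N#Cc1ccc(C2CCCc3cncn32)cc1	4	fadrozole
CC12CCC3C(CCC4=C(O)C(=O)CCC34C)C1CCC2=O	5	formestane
C=C1CC2C(CCC3(C)C2CCC3=O)C2(C)C=CC(=O)C=C12	6	exemestane
CCC1(c2ccc(N)cc2)CCC(=O)NC1=O	7	aminoglutethimide
CC12CCC3C(CCC4=CC(=O)CCC43C)C1CCC(=O)O2	8	testolactone
OC(c1ccc(F)cc1)Cn1ccnc1	9	imidazophenyl
O=C(c1ccc(Cl)cc1)Cn1cncn1	10	triazolylketone
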