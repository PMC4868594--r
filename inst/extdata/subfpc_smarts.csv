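id,smarts,label
SubFPC1,[CX4H3][#6],primary carbon
SubFPC2,[CX4H2]([#6])[#6],secondary carbon
SubFPC3,[CX4H1]([#6])([#6])[#6],tertiary carbon
SubFPC4,[CX4]([#6])([#6])([#6])[#6],quaternary carbon
SubFPC5,[CX3]=[CX3],alkene
SubFPC8,[CX2]#[CX2],alkyne
SubFPC12,[OX2H][CX4],alcohol
SubFPC13,[OX2H][CX4H2],primary alcohol
SubFPC14,[OX2H][CX4H1],secondary alcohol
SubFPC15,[OX2H][CX4]([#6])([#6])[#6],tertiary alcohol
SubFPC16,[OX2]([CX4])[CX4],dialkylether
SubFPC19,[OX2](c)[CX4],alkylarylether
SubFPC20,[SX2](c)[CX4],alkylarylthioether
SubFPC23,[NX3H2][CX4],primary aliphatic amine
SubFPC24,[NX3H1]([CX4])[CX4],secondary aliphatic amine
SubFPC25,[NX3H0]([CX4])([CX4])[CX4],tertiary aliphatic amine
SubFPC27,[NX3H2]c,primary aromatic amine
SubFPC35,[NX4+],ammonium
SubFPC38,[SX2]([#6])[#6],thioether
SubFPC42,[OX2H]c,phenol
SubFPC49,[#6][CX3](=[OX1])[#6],ketone
SubFPC50,[CX3H1](=[OX1])[#6],aldehyde
SubFPC56,[NX1]#[CX2][#6],nitrile
SubFPC72,[OX2H][CX3]=[CX3],enol
SubFPC76,[NX3][CX3]=[CX3],enamine
SubFPC84,[CX3](=[OX1])[OX2H],carboxylic acid
SubFPC85,[CX3](=[OX1])[OX2][#6],carboxylic ester
SubFPC87,[CX3](=[OX1])[NX3],amide
SubFPC88,[CX3](=[OX1])[#7;!$([#7]~[!#6;!#1])],carboxylic acid amide derivative
SubFPC89,"[CX3](=[OX1])[#8X2,F,Cl,Br,I]",carboxylic acid ester or halide derivative
SubFPC96,[CX3](=[SX1])[SX2][#6],carbodithioic ester
SubFPC105,[CX3](=[OX1])[NX3H1][CX3](=[OX1]),imide acidic
SubFPC134,[CX1-]#[NX2+],isonitrile
SubFPC135,[CX3]=[CX3][CX3]=[OX1],vinylogous carbonyl or carboxyl derivative
SubFPC137,[CX3]=[CX3][OX2][CX4],vinylogous ester
SubFPC170,Fc,arylfluoride
SubFPC171,Clc,arylchloride
SubFPC180,"[$([nX2H0+0]),$([NX3H0+0;!$([NX3]=*);!$([NX3][CX3]=[OX1,SX1,NX2])])]",hetero N basic no H
SubFPC181,"[$([nX3H1]),$([nX3+]),$([NX3H1][CX3]=[OX1])]",hetero N nonbasic
SubFPC184,[a;!c],heteroaromatic
SubFPC275,[!#6;!#1;R],heterocyclic
SubFPC287,[CX3]=[CX3][CX3]=[CX3],conjugated double bond
SubFPC295,"[#6]~[#7,#8,#16]",C ONS bond
SubFPC296,"[+1,+2,+3,+4,+5,+6,+7,-1,-2,-3,-4,-5,-6,-7]",charged
SubFPC297,"[-1,-2,-3,-4,-5,-6,-7]",anion
SubFPC298,"[+1,+2,+3,+4,+5,+6,+7]",cation
SubFPC299,"[$([-1,-2,-3,-4,-5,-6,-7]),$([+1,+2,+3,+4,+5,+6,+7])]",salt
SubFPC300,[CX4!H0][CX3]=[OX1],"1,3-tautomerizable"
SubFPC301,[CX4!H0][CX3]=[CX3][CX3]=[OX1],"1,5-tautomerizable"
SubFPC302,[!$(*#*)&!D1]-!@[!$(*#*)&!D1],rotatable bond
SubFPC303,"[CX3]=[CX3][CX3]=[OX1,NX2]",Michael acceptor
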