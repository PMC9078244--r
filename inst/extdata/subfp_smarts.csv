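code,smarts,description
SubFP1,[CX4H3][#6],Primary carbon
SubFP2,[CX4H2]([#6])[#6],Secondary carbon
SubFP5,[CX3]=[CX3],Alkene
SubFP16,[OX2]([CX4])[CX4],Dialkylether
SubFP18,[OX2](c)[CX4],Alkylarylether
SubFP49,[#6][CX3](=[OX1])[#6],Ketone
SubFP135,"[#8,#7,#16,F,Cl,Br,I][#6X3]=[#6X3][#6X3]=[OX1]",Vinylogous carbonyl
SubFP137,[#6][OX2][#6X3]=[#6X3][#6X3]=[OX1],Vinylogous ester
SubFP139,"[F,Cl,Br,I][#6X3]=[#6X3][#6X3]=[OX1]",Vinylogous halide
SubFP171,[Cl][c],Aryl chloride
SubFP173,[Br][c],Arylbromide
SubFP274,a,Aromatic
SubFP275,"[!#6;!#1;R]",Heterocyclic
SubFP287,[*]=[*][*]=[*],Conjugated double bond
SubFP295,"[#6]~[#7,#8,#16]",C ONS bond
SubFP300,"[O,S,N]=[#6][#6;!H0]","1,3-Tautomerizable"
SubFP301,"[O,S,N]=[#6][#6]=[#6][#6;!H0]","1,5-Tautomerizable"
SubFP302,"[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",Rotatable bond
SubFP303,"[CX3]=[CX3][$([CX3]=[OX1]),$(C#N),$([SX4](=[OX1])=[OX1])]",Michael acceptor
SubFP307,"[$([*@](~*)(~*)(*)*),$([*@@](~*)(~*)(*)*),$([*@H](*)(*)*),$([*@@H](*)(*)*)]",Chiral center specified
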