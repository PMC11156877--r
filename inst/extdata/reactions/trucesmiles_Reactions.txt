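# 12 variants: {aryl-ZH, aryl-sulfonamide} x {R2=H, R2!=H} x chain 0/1/2
REACTION	TS01	[a:1][OX2H1,NX3H2,SX2H1:2].[F,Cl,Br,I][$(C=O):3][CX4H2!R,CX4H3!R:5][H]>>[*:5]([a:1])([$(C=O):3][*:2])	TS_A_ZH,TS_B_H0	reagent_a=zh	chain=0	product_class=nonchiral
REACTION	TS02	[a:1][OX2H1,NX3H2,SX2H1:2].[F,Cl,Br,I][$(C=O):3][CX4H2:6][CX4H2!R,CX4H3!R:5][H]>>[*:5]([a:1])([*:6][$(C=O):3][*:2])	TS_A_ZH,TS_B_H1	reagent_a=zh	chain=1	product_class=nonchiral
REACTION	TS03	[a:1][OX2H1,NX3H2,SX2H1:2].[F,Cl,Br,I][$(C=O):3][CX4H2:7][CX4H2:6][CX4H2!R,CX4H3!R:5][H]>>[*:5]([a:1])([*:7][*:6][$(C=O):3][*:2])	TS_A_ZH,TS_B_H2	reagent_a=zh	chain=2	product_class=nonchiral
REACTION	TS04	[a:1][OX2H1,NX3H2,SX2H1:2].[F,Cl,Br,I][$(C=O):3][CX4H1!R:5]([H])([*:9])>>[*:5]([*:9])([a:1])([$(C=O):3][*:2])	TS_A_ZH,TS_B_R0	reagent_a=zh	chain=0	product_class=chiral
REACTION	TS05	[a:1][OX2H1,NX3H2,SX2H1:2].[F,Cl,Br,I][$(C=O):3][CX4H2:6][CX4H1!R:5]([H])([*:9])>>[*:5]([*:9])([a:1])([*:6][$(C=O):3][*:2])	TS_A_ZH,TS_B_R1	reagent_a=zh	chain=1	product_class=chiral
REACTION	TS06	[a:1][OX2H1,NX3H2,SX2H1:2].[F,Cl,Br,I][$(C=O):3][CX4H2:7][CX4H2:6][CX4H1!R:5]([H])([*:9])>>[*:5]([*:9])([a:1])([*:7][*:6][$(C=O):3][*:2])	TS_A_ZH,TS_B_R2	reagent_a=zh	chain=2	product_class=chiral
REACTION	TS07	[a:1][$([SX4](=[OX1])(=[OX1])[NX3H2])].[F,Cl,Br,I][$(C=O):3][CX4H2!R,CX4H3!R:5][H]>>[*:5]([a:1])([$(C=O):3]O)	TS_A_SULF,TS_B_H0	reagent_a=sulf	chain=0	product_class=nonchiral
REACTION	TS08	[a:1][$([SX4](=[OX1])(=[OX1])[NX3H2])].[F,Cl,Br,I][$(C=O):3][CX4H2:6][CX4H2!R,CX4H3!R:5][H]>>[*:5]([a:1])([*:6][$(C=O):3]O)	TS_A_SULF,TS_B_H1	reagent_a=sulf	chain=1	product_class=nonchiral
REACTION	TS09	[a:1][$([SX4](=[OX1])(=[OX1])[NX3H2])].[F,Cl,Br,I][$(C=O):3][CX4H2:7][CX4H2:6][CX4H2!R,CX4H3!R:5][H]>>[*:5]([a:1])([*:7][*:6][$(C=O):3]O)	TS_A_SULF,TS_B_H2	reagent_a=sulf	chain=2	product_class=nonchiral
REACTION	TS10	[a:1][$([SX4](=[OX1])(=[OX1])[NX3H2])].[F,Cl,Br,I][$(C=O):3][CX4H1!R:5]([H])([*:9])>>[*:5]([*:9])([a:1])([$(C=O):3]O)	TS_A_SULF,TS_B_R0	reagent_a=sulf	chain=0	product_class=chiral
REACTION	TS11	[a:1][$([SX4](=[OX1])(=[OX1])[NX3H2])].[F,Cl,Br,I][$(C=O):3][CX4H2:6][CX4H1!R:5]([H])([*:9])>>[*:5]([*:9])([a:1])([*:6][$(C=O):3]O)	TS_A_SULF,TS_B_R1	reagent_a=sulf	chain=1	product_class=chiral
REACTION	TS12	[a:1][$([SX4](=[OX1])(=[OX1])[NX3H2])].[F,Cl,Br,I][$(C=O):3][CX4H2:7][CX4H2:6][CX4H1!R:5]([H])([*:9])>>[*:5]([*:9])([a:1])([*:7][*:6][$(C=O):3]O)	TS_A_SULF,TS_B_R2	reagent_a=sulf	chain=2	product_class=chiral
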