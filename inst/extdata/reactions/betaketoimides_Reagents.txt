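# beta-keto-imides: dioxinone (reagent A) + primary/secondary amide (reagent B)
# Reagent A precursors: free and O-protected beta-keto acids, converted to
# the dioxinone by a one-component precursor transform.
SYNTHON	BKI_A	C1([CH3])([CH3])OC(=O)C([H])=CO1
TAG	BKI_A	BKI_A
SYNTHON	BKI_A_PRE_ACID	[OH]C([CH2][C;!R]([C;!c])=O)=O
TAG	BKI_A_PRE_ACID	BKI_A
PRECURSOR	BKI_A_PRE_ACID	[OX2H1][C:1](=[O:2])[CX4H2:3][C:4]=[O:5]>>[C:1]1(=[O:2])[CH1:3]=[C:4][O:5]C(C)(C)O1
SYNTHON	BKI_A_PRE_TBU	O=C([CH2][C;!R]([C;!c])=O)OC([CH3])([CH3])[CH3]
TAG	BKI_A_PRE_TBU	BKI_A
PRECURSOR	BKI_A_PRE_TBU	[OX2](C([CH3])([CH3])[CH3])[C:1](=[O:2])[CX4H2:3][C:4]=[O:5]>>[C:1]1(=[O:2])[CH1:3]=[C:4][O:5]C(C)(C)O1
SYNTHON	BKI_A_PRE_ME	O=C([CH2][C;!R]([C;!c])=O)O[CH3]
TAG	BKI_A_PRE_ME	BKI_A
PRECURSOR	BKI_A_PRE_ME	[OX2]([CH3])[C:1](=[O:2])[CX4H2:3][C:4]=[O:5]>>[C:1]1(=[O:2])[CH1:3]=[C:4][O:5]C(C)(C)O1
SYNTHON	BKI_A_PRE_ET	O=C([CH2][C;!R]([C;!c])=O)O[CH2][CH3]
TAG	BKI_A_PRE_ET	BKI_A
PRECURSOR	BKI_A_PRE_ET	[OX2]([CH2][CH3])[C:1](=[O:2])[CX4H2:3][C:4]=[O:5]>>[C:1]1(=[O:2])[CH1:3]=[C:4][O:5]C(C)(C)O1
SYNTHON	BKI_A_PRE_BN	O=C([CH2][C;!R]([C;!c])=O)O[CH2][c]1[cH1][cH1][cH1][cH1][cH1]1
TAG	BKI_A_PRE_BN	BKI_A
PRECURSOR	BKI_A_PRE_BN	[OX2]([CH2]c1ccccc1)[C:1](=[O:2])[CX4H2:3][C:4]=[O:5]>>[C:1]1(=[O:2])[CH1:3]=[C:4][O:5]C(C)(C)O1
SYNTHON	BKI_B	[CX3]([NX3;H2,H1])=O
EXCLUDE	BKI_B	[CX3](=[OX1])[NX3][CX3]=[OX1]
TAG	BKI_B	BKI_B
GLOBAL_EXCLUDE	disallowed_element	[!#1;!#6;!#7;!#8;!#9;!#15;!#16;!#17;!#35;!#53]
GLOBAL_EXCLUDE	acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
GLOBAL_EXCLUDE	aldehyde	[CX3H1]=[OX1]
GLOBAL_EXCLUDE	anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]
GLOBAL_EXCLUDE	isocyanate	[NX2]=C=[OX1]
GLOBAL_EXCLUDE	isothiocyanate	[NX2]=C=S
GLOBAL_EXCLUDE	azide	N=[N+]=[N-]
GLOBAL_EXCLUDE	diazo	[CX3]=[N+]=[N-]
GLOBAL_EXCLUDE	diazonium	[N+]#N
GLOBAL_EXCLUDE	nitroso	[#6][NX2]=[OX1]
GLOBAL_EXCLUDE	peroxide	[OX2][OX2]
GLOBAL_EXCLUDE	epoxide	C1OC1
GLOBAL_EXCLUDE	aziridine	C1NC1
GLOBAL_EXCLUDE	thiol	[SX2H]
GLOBAL_EXCLUDE	disulfide	[SX2][SX2]
GLOBAL_EXCLUDE	sulfonyl_halide	[SX4](=[OX1])(=[OX1])[F,Cl,Br,I]
GLOBAL_EXCLUDE	phosphorus_halide	[#15][F,Cl,Br,I]
GLOBAL_EXCLUDE	nitrogen_halide	[#7][F,Cl,Br,I]
GLOBAL_EXCLUDE	alkyl_halide	[CX4][Cl,Br,I]
GLOBAL_EXCLUDE	alpha_halo_carbonyl	[CX3](=[OX1])[CX4][Cl,Br,I]
GLOBAL_EXCLUDE	quaternary_nitrogen	[NX4+]
GLOBAL_EXCLUDE	hydrazine	[NX3;H1,H2][NX3;H1,H2]
GLOBAL_EXCLUDE	acyclic_imine	[CX3;!R]=[NX2;!R]
GLOBAL_EXCLUDE	ketene	[CX3]=[CX2]=[OX1]
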