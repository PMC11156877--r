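# [4+2]-cycloaddition: same reagent A as the [2+2]; reagent B is a
# furan, cyclopentadiene or N-substituted pyrrole (three hindrance
# classes each: R1/R3 both H, one H, neither H)
SYNTHON	W42_A_ANH	[#6][CX3D3!R](=O)[O!R][CX3D3!R](=O)[#6]
SYMMETRIC	W42_A_ANH	[*:1]C(=O)OC(=O)[*:2]
TAG	W42_A_ANH	W42_A_ANH
SYNTHON	W42_A_ACL	[#6][CX3D3!R](=O)Cl
TAG	W42_A_ACL	W42_A_ACL
SYNTHON	W42_B_FUR	[cX3H1]1o[cX3H1][cX3H0&$(c!@[#6]),cX3H1][cX3H0&$(c!@[#6]),cX3H1]1
SYNTHON	W42_B_FUR	[cX3H0&$(c!@[#6])]1o[cX3H1][cX3H0&$(c!@[#6]),cX3H1][cX3H0&$(c!@[#6]),cX3H1]1
SYNTHON	W42_B_FUR	[cX3H0&$(c!@[#6])]1o[cX3H0&$(c!@[#6])][cX3H0&$(c!@[#6]),cX3H1][cX3H0&$(c!@[#6]),cX3H1]1
TAG	W42_B_FUR	W42_B_FUR
SYNTHON	W42_B_CP	[CX3H1]1=[CX3H0&$(C!@[#6]),CX3H1][CX3H0&$(C!@[#6]),CX3H1]=[CX3H1][CX4H2]1
SYNTHON	W42_B_CP	[CX3H0&$(C!@[#6])]1=[CX3H0&$(C!@[#6]),CX3H1][CX3H0&$(C!@[#6]),CX3H1]=[CX3H1][CX4H2]1
SYNTHON	W42_B_CP	[CX3H0&$(C!@[#6])]1=[CX3H0&$(C!@[#6]),CX3H1][CX3H0&$(C!@[#6]),CX3H1]=[CX3H0&$(C!@[#6])][CX4H2]1
TAG	W42_B_CP	W42_B_CP
SYNTHON	W42_B_PYR	[cX3H1]1n([#6!c])[cX3H1][cX3H0&$(c!@[#6]),cX3H1][cX3H0&$(c!@[#6]),cX3H1]1
SYNTHON	W42_B_PYR	[cX3H0&$(c!@[#6])]1n([#6!c])[cX3H1][cX3H0&$(c!@[#6]),cX3H1][cX3H0&$(c!@[#6]),cX3H1]1
SYNTHON	W42_B_PYR	[cX3H0&$(c!@[#6])]1n([#6!c])[cX3H0&$(c!@[#6])][cX3H0&$(c!@[#6]),cX3H1][cX3H0&$(c!@[#6]),cX3H1]1
TAG	W42_B_PYR	W42_B_PYR
GLOBAL_EXCLUDE	disallowed_element	[!#1;!#6;!#7;!#8;!#9;!#15;!#16;!#17;!#35;!#53]
GLOBAL_EXCLUDE	aldehyde	[CX3H1]=[OX1]
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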