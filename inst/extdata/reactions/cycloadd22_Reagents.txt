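# [2+2]-cycloaddition via 1,2-acyloxycyclohexadienes generated in situ
# from anhydrides or acyl chlorides; reagent B: mono- or 1,1-disubstituted
# electron-deficient olefin or styrene
SYNTHON	W22_A_ANH	[#6][CX3D3!R](=O)[O!R][CX3D3!R](=O)[#6]
SYMMETRIC	W22_A_ANH	[*:1]C(=O)OC(=O)[*:2]
TAG	W22_A_ANH	W22_A_ANH
SYNTHON	W22_A_ACL	[#6][CX3D3!R](=O)Cl
TAG	W22_A_ACL	W22_A_ACL
SYNTHON	W22_B_1	[CX3H2;!R]=[CX3H1;!R]([$([CX3](=[OX1])[#6,$([OX2][#6])]),$([CX2]#[NX1]),c])
TAG	W22_B_1	W22_B_1
SYNTHON	W22_B_11	[CX3H2;!R]=[CX3;!R]([#6])([$([CX3](=[OX1])[#6,$([OX2][#6])]),$([CX2]#[NX1]),c])
TAG	W22_B_11	W22_B_11
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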