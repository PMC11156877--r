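# Default global reagent exclusion rules: reactive, unstable or otherwise
# unwanted functional groups screened out of building-block catalogs before
# enumeration, in the spirit of the ZINC reactivity filters.
#
# NON-CANONICAL: this list is an editable approximation curated for this
# toolkit; the exact rule set used to build the original library was pruned
# per reaction on a case-by-case basis and is not published. Each packaged
# reaction ships its own pruned copy of these rules in its reagents file
# (rules that describe that reaction's own reactive groups are dropped).
#
# Format: name <TAB> SMARTS
disallowed_element	[!#1;!#6;!#7;!#8;!#9;!#15;!#16;!#17;!#35;!#53]
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
aldehyde	[CX3H1]=[OX1]
anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]
isocyanate	[NX2]=C=[OX1]
isothiocyanate	[NX2]=C=S
azide	N=[N+]=[N-]
diazo	[CX3]=[N+]=[N-]
diazonium	[N+]#N
nitroso	[#6][NX2]=[OX1]
peroxide	[OX2][OX2]
epoxide	C1OC1
aziridine	C1NC1
thiol	[SX2H]
disulfide	[SX2][SX2]
sulfonyl_halide	[SX4](=[OX1])(=[OX1])[F,Cl,Br,I]
phosphorus_halide	[#15][F,Cl,Br,I]
nitrogen_halide	[#7][F,Cl,Br,I]
alkyl_halide	[CX4][Cl,Br,I]
alpha_halo_carbonyl	[CX3](=[OX1])[CX4][Cl,Br,I]
quaternary_nitrogen	[NX4+]
hydrazine	[NX3;H1,H2][NX3;H1,H2]
acyclic_imine	[CX3;!R]=[NX2;!R]
ketene	[CX3]=[CX2]=[OX1]
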