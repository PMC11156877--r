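# SYNTHETIC Brenk-style structural alert catalog.
# Curated approximation, authored for this package, of the unwanted-group
# families described by Brenk R et al., ChemMedChem 2008, 3:435-444
# (reactive, potentially toxic or pharmacokinetically unfavourable motifs).
# The original supplementary SMARTS list is NOT redistributed here; hit
# rates from this catalog are indicative, not reference values.
# Format: name <TAB> SMARTS
isothiocyanate	N=C=S
isocyanate	N=C=O
aldehyde	[CX3H1](=[OX1])[#6]
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
alkyl_halide	[CX4][Cl,Br,I]
anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]
michael_acceptor_enone	[CX3]=[CX3][CX3]=[OX1]
michael_acceptor_nitrile	[CX3H2]=[CX3][CX2]#[NX1]
nitro_group	[#6][NX3+](=[OX1])[OX1-]
nitro_group_uncharged	[#6][NX3](=[OX1])=[OX1]
azo_group	[#6][NX2]=[NX2][#6]
azide	N=[N+]=[N-]
diazo	[CX3]=[N+]=[N-]
diazonium	[N+]#N
oxime	[CX3]=[NX2][OX2H1]
hydrazine	[NX3;H1,H2][NX3;H1,H2]
hydrazone	[CX3]=[NX2][NX3]
acyclic_imine	[CX3;!R]=[NX2;!R][#6]
nitroso	[#6][NX2]=[OX1]
thiol	[SX2H]
disulfide	[SX2][SX2]
peroxide	[OX2][OX2]
epoxide	C1OC1
aziridine	C1NC1
thiirane	C1SC1
phosphorus_atom	[#15]
sulfonyl_halide	[SX4](=[OX1])(=[OX1])[F,Cl,Br,I]
sulfonic_ester	[SX4](=[OX1])(=[OX1])[OX2][#6]
acyl_cyanide	[CX3](=[OX1])[CX2]#[NX1]
thioester	[CX3](=[OX1])[SX2]
thiourea	[NX3][CX3](=[SX1])[NX3]
thioamide	[NX3][CX3]=[SX1]
quaternary_nitrogen	[NX4+]
trichloromethyl	[CX4](Cl)(Cl)Cl
beta_lactam	[CX3]1(=[OX1])[CX4][CX4][NX3]1
maleimide	[CX3]1(=[OX1])[CX3]=[CX3][CX3](=[OX1])[NX3]1
quinone	[CX3]1(=[OX1])[CX3]=[CX3][CX3](=[OX1])[CX3]=[CX3]1
conjugated_triene	[CX3]=[CX3][CX3]=[CX3][CX3]=[CX3]
heavy_or_unusual_element	[!#1;!#6;!#7;!#8;!#9;!#14;!#15;!#16;!#17;!#35;!#53]
hydroxamic_acid	[CX3](=[OX1])[NX3][OX2H1]
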