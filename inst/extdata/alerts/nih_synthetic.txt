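# SYNTHETIC NIH-style structural alert catalog.
# Curated approximation, authored for this package, of the NIH MLSMR-type
# filters for reactive or otherwise undesired functional groups and common
# fluorescent cores (cf. Jadhav A et al., J Med Chem 2010, 53:37-51;
# Doveston R et al., Drug Discov Today 2015). The original pattern list is
# NOT redistributed here; hit rates from this catalog are indicative only.
# Format: name <TAB> SMARTS
aldehyde	[CX3H1](=[OX1])[#6]
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]
isocyanate	N=C=O
isothiocyanate	N=C=S
epoxide	C1OC1
aziridine	C1NC1
primary_alkyl_halide	[CX4H2][Cl,Br,I]
benzylic_halide	[cX3][CX4H2][Cl,Br,I]
vinyl_ketone	[CX3H2]=[CX3][CX3](=[OX1])[#6]
acrylate	[CX3H2]=[CX3][CX3](=[OX1])[OX2][#6]
acrylonitrile	[CX3H2]=[CX3][CX2]#[NX1]
vinyl_sulfone	[CX3H2]=[CX3][SX4](=[OX1])=[OX1]
halopyridine	[F,Cl,Br,I][c;$(c1ncccc1)]
nitro_group	[#6][NX3+](=[OX1])[OX1-]
nitro_group_uncharged	[#6][NX3](=[OX1])=[OX1]
azo_group	[#6][NX2]=[NX2][#6]
oxime	[CX3]=[NX2][OX2H1]
hydrazine	[NX3;H1,H2][NX3;H1,H2]
thiol	[SX2H]
disulfide	[SX2][SX2]
peroxide	[OX2][OX2]
thiourea	[NX3][CX3](=[SX1])[NX3]
thioamide	[NX3][CX3]=[SX1]
hydroxamic_acid	[CX3](=[OX1])[NX3][OX2H1]
catechol	[OX2H1]c1ccccc1[OX2H1]
rhodanine_core	[CX3]1(=[OX1])[CX4,CX3][SX2][CX3](=[SX1])[NX3]1
acridine_core	c1ccc2nc3ccccc3cc2c1
anthracene_core	c1ccc2cc3ccccc3cc2c1
coumarin_core	[CX3]1(=[OX1])[CX3]=[CX3]c2ccccc2[OX2]1
xanthene_core	C1c2ccccc2Oc2ccccc21
quinone	[CX3]1(=[OX1])[CX3]=[CX3][CX3](=[OX1])[CX3]=[CX3]1
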