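REACTION	W22_1	C(=O)(OC=O)[*:1].[CX3H2]=C([*:2])([*:3])>>C1(=C2C(CCC1)C(C2)([*:2])[*:3])OC([*:1])=O	W22_A_ANH,W22_B_1	olefin=1sub
REACTION	W22_2	ClC(=O)[*:1].[CX3H2]=C([*:2])([*:3])>>C1(=C2C(CCC1)C(C2)([*:2])[*:3])OC([*:1])=O	W22_A_ACL,W22_B_1	olefin=1sub
REACTION	W22_3	C(=O)(OC=O)[*:1].[CX3H2]=C([*:2])([*:3])>>C1(=C2C(CCC1)C(C2)([*:2])[*:3])OC([*:1])=O	W22_A_ANH,W22_B_11	olefin=11sub
REACTION	W22_4	ClC(=O)[*:1].[CX3H2]=C([*:2])([*:3])>>C1(=C2C(CCC1)C(C2)([*:2])[*:3])OC([*:1])=O	W22_A_ACL,W22_B_11	olefin=11sub
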