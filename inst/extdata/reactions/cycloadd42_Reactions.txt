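REACTION	W42_1	C(=O)(OC=O)[*:1].[c:2]1[o:3][c:4][c:5][c:6]1>>C1(=C2C(CCC1)[C:2]3[O:3][C:4]2[C:5]=[C:6]3)OC(=O)[*:1]	W42_A_ANH,W42_B_FUR	ring=furan
REACTION	W42_2	ClC(=O)[*:1].[c:2]1[o:3][c:4][c:5][c:6]1>>C1(=C2C(CCC1)[C:2]3[O:3][C:4]2[C:5]=[C:6]3)OC(=O)[*:1]	W42_A_ACL,W42_B_FUR	ring=furan
REACTION	W42_3	C(=O)(OC=O)[*:1].[C:2]=1[C:3][C:4]=[C:5][C:6]1>>C1(=C2C(CCC1)[C:2]3[C:3][C:4]2[C:5]=[C:6]3)OC(=O)[*:1]	W42_A_ANH,W42_B_CP	ring=cyclopentadiene
REACTION	W42_4	ClC(=O)[*:1].[C:2]=1[C:3][C:4]=[C:5][C:6]1>>C1(=C2C(CCC1)[C:2]3[C:3][C:4]2[C:5]=[C:6]3)OC(=O)[*:1]	W42_A_ACL,W42_B_CP	ring=cyclopentadiene
REACTION	W42_5	C(=O)(OC=O)[*:1].[c:2]1[n:3][c:4][c:5][c:6]1>>C1(=C2C(CCC1)[C:2]3[N:3][C:4]2[C:5]=[C:6]3)OC(=O)[*:1]	W42_A_ANH,W42_B_PYR	ring=pyrrole
REACTION	W42_6	ClC(=O)[*:1].[c:2]1[n:3][c:4][c:5][c:6]1>>C1(=C2C(CCC1)[C:2]3[N:3][C:4]2[C:5]=[C:6]3)OC(=O)[*:1]	W42_A_ACL,W42_B_PYR	ring=pyrrole
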