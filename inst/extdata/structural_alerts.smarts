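# Structural alert patterns (curated subset of the published Brenk alert
# set, rewritten as standard SMARTS; user-replaceable).
# Format: SMARTS <whitespace> alert_name.  '#' starts a comment.
[O-][N+](=O)*	nitro_group
[NX2]=[OX1]	nitroso
[NX3][NX2]=[OX1]	N-nitroso
[CX3H1](=O)[#6]	aldehyde
[CX3](=[OX1])[F,Cl,Br,I]	acid_halide
[CX3](=[OX1])[OX2][CX3]=[OX1]	anhydride
[CX4][Br,I]	alkyl_halide
[CX3](=[OX1])[CX4][Cl,Br,I]	alpha_halo_ketone
[CX3]=[CX3][CX3]=[OX1]	michael_acceptor_enone
[CX3]=[CX3]C#N	michael_acceptor_nitrile
[CX4]1[OX2][CX4]1	epoxide
[CX4]1[NX3][CX4]1	aziridine
N=[N+]=[N-]	azide
C=[N+]=[N-]	diazo
[#6][N+]#N	diazonium
[#6]N=N[#6]	azo_group
N=C=O	isocyanate
N=C=S	isothiocyanate
[SX2]C#N	thiocyanate
[NX3]C#N	cyanamide
[NX3][NX3]	hydrazine
[CX3]=[NX2][NX3]	hydrazone
[NX3][OX2H]	hydroxylamine
[CX3]=[NX2][OX2H]	oxime
[CX3]=!@[NX2]	acyclic_imine
[OX2][OX2]	peroxide
[SX2][SX2]	disulfide
[SX2H]	thiol
[SX2][CX3]=[OX1]	thioester
[NX3][CX3]=[SX1]	thioamide_thiourea
[SX4](=[OX1])(=[OX1])[F,Cl,Br,I]	sulfonyl_halide
[#6][SX4](=[OX1])(=[OX1])[OX2][#6]	sulfonic_ester
[#15]	phosphorus
[NX4+]	quaternary_nitrogen
[CX3]1(=[OX1])[CX4][CX4][NX3]1	beta_lactam
[CX2]#[CX2]	triple_bond
[CX3]=[CX3][CX3]=[CX3][CX3]=[CX3]	conjugated_triene
[CX3]=!@[CX3][OX2]	acyclic_enol_ether
c([OX2H])c([OX2H])	catechol
[CH2R0][CH2R0][CH2R0][CH2R0][CH2R0][CH2R0]	aliphatic_long_chain
I	iodine
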