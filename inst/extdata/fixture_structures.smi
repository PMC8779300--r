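# Curated, well-known small-molecule structures for structure-path tests
# and synthetic libraries. Format: SMILES id
CC(=O)Oc1ccccc1C(=O)O aspirin
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
CC(=O)Nc1ccc(O)cc1 paracetamol
COc1ccc2cc(ccc2c1)C(C)C(=O)O naproxen
O=[N+]([O-])c1ccccc1 nitrobenzene
Cc1ncc(n1CCO)[N+](=O)[O-] metronidazole
OC(c1ccc(cc1)[N+](=O)[O-])C(CO)NC(=O)C(Cl)Cl chloramphenicol
CN1CCCC1c1cccnc1 nicotine
CC(C)C1CCC(C)CC1O menthol
CC(=C)C1CCC(C)=CC1 limonene
CC1(C)C2CCC1(C)C(=O)C2 camphor
COc1cc(C=O)ccc1O vanillin
OC(=O)c1ccccc1O salicylic_acid
NC(=O)c1ccccc1 benzamide
CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O warfarin
Nc1ccc(cc1)S(N)(=O)=O sulfanilamide
Oc1ccc(C=CC(=O)O)cc1O caffeic_acid
CC(=CCCC(=CCCC(=CCO)C)C)C farnesol
CC(=CCCC(=CCO)C)C geraniol
c1ccc2[nH]ccc2c1 indole
c1ccc2ccccc2c1 naphthalene
Cc1ccccc1 toluene
Oc1ccccc1 phenol
Nc1ccccc1 aniline
c1ccncc1 pyridine
c1ccoc1 furan
OCC1OC(O)C(O)C(O)C1O glucose
NCC(=O)O glycine
CC(=O)O acetic_acid
c1ccccc1 benzene
CCO ethanol
CCC propane
CC ethane
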