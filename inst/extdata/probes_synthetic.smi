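CC1CC(C)C(O)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1 synthetic_macrolactone_01
CC1CC(C)C(OC2OC(C)CC(O)C2O)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1 synthetic_glycoside_02
CC1CC(C)C(OC(C)=O)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1 synthetic_acetate_03
CC1CC(C)C(OC2OC(C)CC(N(C)C)C2O)CC(=O)CC(C)C(O)C(C)CC(C)C(=O)O1 synthetic_aminosugar_04
CC1CCC(C)C(O)CC(=O)CC(C)C(O)C(C)CC(C=O)CC(C)C(=O)O1 synthetic_aldehyde_05
CC1CC(C)C(O)CC(=O)CC(C)C(OC)C(C)CC(=C)C(=O)O1 synthetic_methoxy_06
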