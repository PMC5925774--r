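# Structural-alert (toxicophore) SMARTS, a small literature-derived set.
# name<TAB>pattern
nitroaromatic	[c][N+](=O)[O-]
aromatic_amine	[c][NX3;H2,H1]
aromatic_nitroso	[c][NX2]=O
azo	[#6][NX2]=[NX2][#6]
nitrosamine	[NX3][NX2]=O
epoxide	C1OC1
aziridine	C1NC1
aldehyde	[CX3H1](=O)[#6]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
quinone	O=C1C=CC(=O)C=C1
alkyl_halide	[CX4][Cl,Br,I]
acyl_halide	[CX3](=O)[Cl,Br,I]
hydrazine	[NX3][NX3]
isocyanate	[NX2]=C=O
thiourea	[NX3]C(=S)[NX3]
polycyclic_aromatic	c1ccc2cc3ccccc3cc2c1
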