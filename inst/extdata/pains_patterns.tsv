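# Compact PAINS substructure catalog: representative SMARTS for the classic
# pan-assay-interference compound classes.  Supply a full published catalog
# via the catalogPath argument of painsScreen() for production screening.
name	smarts
para_quinone	O=C1C=CC(=O)C=C1
ortho_quinone	O=C1C(=O)C=CC=C1
naphthoquinone	O=C1C(=O)c2ccccc2C1
catechol	[OX2H]c1ccccc1[OX2H]
hydroquinone	[OX2H]c1ccc([OX2H])cc1
azo_aryl	cN=Nc
rhodanine	O=C1CSC(=S)N1
ene_rhodanine	O=C1C(=[#6])SC(=S)N1
isothiazolone	O=C1C=CSN1
mannich_phenol	[OX2H]c1ccccc1C[NX3]
hydrazone_aryl	cC=N[NX3]
phenol_hydrazone	[OX2H]c1ccc(C=NN)cc1
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=[#6]
chalcone_enone	cC(=O)C=Cc
aryl_nitroso	cN=O
beta_aminoketone_aryl	cC(=O)CC[NX3]
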