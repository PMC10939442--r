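residue	shift	name
M	15.99491	Oxidation
W	15.99491	Oxidation
P	15.99491	Oxidation (hydroxyproline)
M	31.98983	Dioxidation
W	31.98983	Dioxidation
K	42.01057	Acetyl
K	42.04695	Trimethyl
K	14.01565	Methyl
R	14.01565	Methyl
K	28.03130	Dimethyl
R	28.03130	Dimethyl
S	79.96633	Phospho
T	79.96633	Phospho
Y	79.96633	Phospho
N	0.98402	Deamidation
Q	0.98402	Deamidation
C	57.02146	Carbamidomethyl
K	43.00581	Carbamyl
K	27.99491	Formyl
S	27.99491	Formyl
T	27.99491	Formyl
K	114.04293	GlyGly
K	100.01604	Succinyl
K	86.00039	Malonyl
K	68.02621	Crotonyl
K	56.02621	Propionyl
K	70.04186	Butyryl
C	45.98772	Methylthio
Q	-17.02655	Pyro-Glu (Gln)
E	-18.01056	Pyro-Glu (Glu)
Y	44.98508	Nitro
W	44.98508	Nitro
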