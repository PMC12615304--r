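name	mass	residues	position
Acetyl	42.010565	K	anywhere
Methyl	14.015650	KR	anywhere
Dimethyl	28.031300	KR	anywhere
Trimethyl	42.046950	K	anywhere
Phospho	79.966331	STY	anywhere
GlyGly	114.042927	K	anywhere
Malonyl	86.000394	K	anywhere
Succinyl	100.016044	K	anywhere
Crotonyl	68.026215	K	anywhere
Propionyl	56.026215	K	anywhere
Butyryl	70.041865	K	anywhere
Glutaryl	114.031694	K	anywhere
2-Hydroxyisobutyryl	86.036779	K	anywhere
Lactyl	72.021129	K	anywhere
Formyl	27.994915	K	anywhere
Sulfo	79.956815	Y	anywhere
Nitro	44.985078	Y	anywhere
Oxidation	15.994915	MW	anywhere
Dioxidation	31.989829	MC	anywhere
Deamidation	0.984016	NQ	anywhere
Carbamyl	43.005814	K	anywhere
Palmitoyl	238.229666	CK	anywhere
Myristoyl	210.198366	K	anywhere
Farnesyl	204.187801	C	anywhere
Geranylgeranyl	272.250401	C	anywhere
HexNAc	203.079373	ST	anywhere
Hexose	162.052824	ST	anywhere
Biotinyl	226.077598	K	anywhere
Glutathione	305.068156	C	anywhere
Dehydration	-18.010565	ST	anywhere
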