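modification_name	delta_mass_Da	target_residue
Methyl (K)	14.01565	K
Dimethyl (K)	28.0313	K
Trimethyl (K)	42.04695	K
Formyl (K)	28.0106	K
Acetyl (K)	42.01057	K
Propionyl (K)	56.02621	K
Butyryl (K)	70.04186	K
Crotonyl (K)	68.02621	K
Malonyl (K)	86.00039	K
Succinyl (K)	100.01604	K
Glutaryl (K)	114.03169	K
Hydroxyisobutyryl (K)	86.03678	K
Biotinyl (K)	226.07759	K
GlyGly (K)	114.04293	K
Methyl (R)	14.01565	R
Dimethyl sym (R)	28.0313	R
Dimethyl asym (R)	28.0313	R
Citrullination (R)	0.98402	R
Hydroxyproline (P)	15.99491	P
Phospho (Y)	79.96633	Y
Nitro (Y)	44.98508	Y
O-GlcNAc (S)	203.07937	S
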