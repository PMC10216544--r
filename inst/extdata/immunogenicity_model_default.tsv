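# Default class I pMHC immunogenicity enrichment model.
# Per-residue log-enrichment weights (residues over-represented among
# immunogenic pMHC-I peptides score positive; aromatic/large residues high,
# small polar residues low) and a 9-mer position-importance vector in which
# the MHC anchor positions 1, 2 and the C-terminus carry zero weight and
# the TCR-facing middle (P4-P6) dominates. Layout and constants follow the
# enrichment model of the IEDB class I immunogenicity predictor
# (Calis et al. 2013, PLoS Comput Biol 9:e1003266), transcribed by hand
# from the reference tool's public distribution; every scoring function in
# this package accepts a substitute table with the same three-column layout.
# type	key	weight
residue	A	0.127
residue	C	-0.175
residue	D	0.072
residue	E	0.325
residue	F	0.380
residue	G	0.110
residue	H	0.105
residue	I	0.432
residue	K	-0.700
residue	L	-0.036
residue	M	-0.570
residue	N	-0.021
residue	P	-0.036
residue	Q	-0.376
residue	R	0.168
residue	S	-0.537
residue	T	0.126
residue	V	0.134
residue	W	0.719
residue	Y	-0.012
position	1	0.00
position	2	0.00
position	3	0.10
position	4	0.31
position	5	0.30
position	6	0.29
position	7	0.26
position	8	0.18
position	9	0.00
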