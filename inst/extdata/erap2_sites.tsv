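gene	position	rsid	allele0_residue	allele1_residue
ERAP2	392	rs2549782	G	T
ERAP2	0	rs2248374	A	G
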