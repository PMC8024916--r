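gene	position	rsid	allele0_residue	allele1_residue
ERAP1	56	rs72773968	E	K
ERAP1	127	rs26653	R	P
ERAP1	276	rs26618	I	M
ERAP1	346	rs27895	G	D
ERAP1	349	rs2287987	M	V
ERAP1	528	rs30187	K	R
ERAP1	575	rs10050860	D	N
ERAP1	725	rs17482078	R	Q
ERAP1	730	rs27044	Q	E
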