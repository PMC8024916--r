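species	length	sequence
14mer	14	GLEQLESIINFEKL
13mer	13	LEQLESIINFEKL
12mer	12	EQLESIINFEKL
11mer	11	QLESIINFEKL
10mer	10	LESIINFEKL
9mer	9	ESIINFEKL
8mer	8	SIINFEKL
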