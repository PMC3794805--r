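group	residue	pk
nterm	default	7.50
nterm	A	7.59
nterm	E	7.70
nterm	M	7.00
nterm	P	8.36
nterm	S	6.93
nterm	T	6.82
nterm	V	7.44
cterm	default	3.55
sidechain	C	9.00
sidechain	D	4.05
sidechain	E	4.45
sidechain	H	5.98
sidechain	K	10.00
sidechain	R	12.00
sidechain	Y	10.00
sidechain_cterm	D	4.55
sidechain_cterm	E	4.75
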