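residue	codon
A	GCA
R	AGA
N	AAC
D	GAC
C	TGC
E	GAA
Q	CAA
G	GGA
H	CAC
I	ATA
L	CTA
K	AAA
M	ATG
F	TTC
P	CCA
S	AGC
T	ACA
W	TGG
Y	TAC
V	GTA
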