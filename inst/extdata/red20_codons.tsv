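aa	codon
F	TTC
L	CTC
I	ATC
M	ATG
V	GTA
S	AGC
P	CCG
T	ACG
A	GCC
Y	TAC
H	CAC
Q	CAG
N	AAC
K	AAA
D	GAC
E	GAA
C	TGC
W	TGG
R	CGC
G	GGA
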