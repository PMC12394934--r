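# background amino-acid composition for rice bran protein
# literature-style midpoint abundances (percent of residues); synthetic
# reference profile shipped as the default background for enrichment ratios
residue	percent
A	6.0
C	1.5
D	5.0
E	10.0
F	4.5
G	6.5
H	2.0
I	4.0
K	4.0
L	7.5
M	2.0
N	4.0
P	9.0
Q	4.0
R	7.0
S	8.5
T	4.0
V	6.0
W	1.0
Y	3.5
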