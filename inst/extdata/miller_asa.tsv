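# Reference solvent-accessible surface areas (A^2) of residue X in an
# extended Gly-X-Gly tripeptide, after Miller, Janin, Lesk & Chothia (1987).
amino_acid	reference_asa
A	113
R	241
N	158
D	151
C	140
Q	189
E	183
G	85
H	194
I	182
L	180
K	211
M	204
F	218
P	143
S	122
T	146
W	259
Y	229
V	160
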