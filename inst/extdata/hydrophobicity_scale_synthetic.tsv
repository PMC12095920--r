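# synthetic stand-in hydrophobicity scale v1
# min-max normalisation of Kyte-Doolittle to [0,1]; NOT the learned
# coarse-grained scale used in production force fields
residue	value
A	0.7
C	0.7778
D	0.1111
E	0.1111
F	0.8111
G	0.4556
H	0.1444
I	1.0
K	0.0667
L	0.9222
M	0.7111
N	0.1111
P	0.3222
Q	0.1111
R	0.0
S	0.4111
T	0.4222
V	0.9667
W	0.4
Y	0.3556
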