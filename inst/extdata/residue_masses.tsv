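residue	monoisotopic	average
G	57.021464	57.05140
A	71.037114	71.07802
S	87.032028	87.07742
P	97.052764	97.11537
V	99.068414	99.13125
T	101.047678	101.10404
C	103.009185	103.14281
L	113.084064	113.15787
I	113.084064	113.15787
N	114.042927	114.10280
D	115.026943	115.08757
Q	128.058578	128.12942
K	128.094963	128.17252
E	129.042593	129.11418
M	131.040485	131.19604
H	137.058912	137.13952
F	147.068414	147.17420
R	156.101111	156.18592
Y	163.063329	163.17360
W	186.079313	186.21031
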