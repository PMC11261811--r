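aa	value
A	0.095
R	-0.485
N	-0.405
D	-0.58
C	0.345
Q	-0.3
E	-0.665
G	-0.165
H	-0.385
I	0.75
L	0.53
K	-0.52
M	0.215
F	0.47
P	-0.385
S	-0.205
T	0.025
W	0.095
Y	0.105
V	0.77
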