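aa	sc_diameter	sc_mass	ca_r_bond
A	3.1	15.03	1.5
R	4.7	100.14	4.1
N	3.9	58.06	2.5
D	3.8	59.04	2.5
C	3.6	47.1	2.1
Q	4.2	72.09	3
E	4.1	73.07	3
G	2	1.01	1.1
H	4.4	81.1	3.1
I	4.4	57.11	2.3
L	4.4	57.11	2.6
K	4.4	72.13	3.5
M	4.4	75.15	3
F	4.7	91.13	3.4
P	3.7	41.07	1.9
S	3.3	31.03	1.9
T	3.7	45.06	1.9
W	5.1	130.17	3.9
Y	4.8	107.13	3.9
V	4	43.09	2
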