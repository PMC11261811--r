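aa	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-2.093	0	0	0	-0.252	0	0	-0.115	0	-0.322	-0.286	0	-0.226	-0.276	0	-0.097	-0.179	-0.198	-0.2	-0.325
R	0	1	0	-0.6	0	0	-0.6	0	0	0	0	1	0	0	0	0	0	0	0	0
N	0	0	-1.5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
D	0	-0.6	0	1	0	0	1	0	0	0	0	-0.6	0	0	0	0	0	0	0	0
C	-0.252	0	0	0	-0.322	0	0	-0.148	0	-0.411	-0.366	0	-0.288	-0.352	0	-0.124	-0.229	-0.252	-0.256	-0.415
Q	0	0	0	0	0	-1.5	0	0	0	0	0	0	0	0	0	0	0	0	0	0
E	0	-0.6	0	1	0	0	1	0	0	0	0	-0.6	0	0	0	0	0	0	0	0
G	-0.115	0	0	0	-0.148	0	0	-1.702	0	-0.188	-0.167	0	-0.132	-0.161	0	-0.057	-0.105	-0.115	-0.117	-0.19
H	0	0	0	0	0	0	0	0	-1.5	0	0	0	0	0	0	0	0	0	0	0
I	-0.322	0	0	0	-0.411	0	0	-0.188	0	-3.075	-0.467	0	-0.368	-0.45	0	-0.158	-0.292	-0.322	-0.326	-0.53
L	-0.286	0	0	0	-0.366	0	0	-0.167	0	-0.467	-2.745	0	-0.327	-0.4	0	-0.14	-0.26	-0.286	-0.29	-0.471
K	0	1	0	-0.6	0	0	-0.6	0	0	0	0	1	0	0	0	0	0	0	0	0
M	-0.226	0	0	0	-0.288	0	0	-0.132	0	-0.368	-0.327	0	-2.272	-0.315	0	-0.111	-0.205	-0.226	-0.228	-0.371
F	-0.276	0	0	0	-0.352	0	0	-0.161	0	-0.45	-0.4	0	-0.315	-2.955	0	-0.135	-0.25	-0.576	-0.579	-0.454
P	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
S	-0.097	0	0	0	-0.124	0	0	-0.057	0	-0.158	-0.14	0	-0.111	-0.135	0	-1.643	-0.088	-0.097	-0.098	-0.159
T	-0.179	0	0	0	-0.229	0	0	-0.105	0	-0.292	-0.26	0	-0.205	-0.25	0	-0.088	-1.988	-0.179	-0.181	-0.295
W	-0.198	0	0	0	-0.252	0	0	-0.115	0	-0.322	-0.286	0	-0.226	-0.576	0	-0.097	-0.179	-2.393	-0.5	-0.325
Y	-0.2	0	0	0	-0.256	0	0	-0.117	0	-0.326	-0.29	0	-0.228	-0.579	0	-0.098	-0.181	-0.5	-2.407	-0.329
V	-0.325	0	0	0	-0.415	0	0	-0.19	0	-0.53	-0.471	0	-0.371	-0.454	0	-0.159	-0.295	-0.325	-0.329	-3.105
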