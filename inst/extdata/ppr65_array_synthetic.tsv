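type	index	res5	resL
P	15	M	K
L	14	A	E
S	13	N	N
P	12	T	D
L	11	I	R
S	10	T	N
P	9	T	N
L	8	A	E
S	7	N	D
P	6	T	D
L	5	T	D
S	4	S	N
P	3	T	D
L	2	V	T
S	1	R	K
P2	P2	K	D
L2	L2	F	E
S2	S2	P	N
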