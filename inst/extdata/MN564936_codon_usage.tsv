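codon	aa	count	rscu_published
UUU	F	67	0.69
UUC	F	128	1.31
UUA	L	83	0.73
UUG	L	38	0.34
CUU	L	98	0.87
CUC	L	128	1.13
CUA	L	265	2.35
CUG	L	66	0.58
AUU	I	83	0.68
AUC	I	176	1.44
AUA	I	107	0.88
AUG	M	62	1
GUU	V	37	0.91
GUC	V	48	1.19
GUA	V	60	1.48
GUG	V	17	0.42
UAU	Y	78	0.77
UAC	Y	125	1.23
UAA	*	122	1.28
UAG	*	86	0.91
CAU	H	89	0.88
CAC	H	114	1.12
CAA	Q	162	1.47
CAG	Q	59	0.53
AAU	N	84	0.68
AAC	N	162	1.32
AAA	K	149	1.35
AAG	K	72	0.65
GAU	D	50	0.85
GAC	D	68	1.15
GAA	E	86	1.25
GAG	E	52	0.75
UCU	S	96	0.97
UCC	S	177	1.78
UCA	S	130	1.31
UCG	S	40	0.4
CCU	P	150	1.19
CCC	P	160	1.26
CCA	P	154	1.22
CCG	P	42	0.33
ACU	T	116	0.91
ACC	T	196	1.54
ACA	T	155	1.22
ACG	T	43	0.34
GCU	A	65	0.78
GCC	A	153	1.84
GCA	A	94	1.13
GCG	A	21	0.25
UGU	C	32	0.79
UGC	C	49	1.21
UGA	*	77	0.81
UGG	W	33	1
CGU	R	34	0.78
CGC	R	33	0.76
CGA	R	44	1.01
CGG	R	28	0.64
AGU	S	45	0.45
AGC	S	107	1.08
AGA	R	66	1.51
AGG	R	57	1.31
GGU	G	38	0.81
GGC	G	47	1.01
GGA	G	63	1.35
GGG	G	39	0.83
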