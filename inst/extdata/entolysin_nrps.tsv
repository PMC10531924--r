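# name: entolysin
# macrocycle_size: 5
index	residue	cdomain	epi_label
1	Leu	CSTART	.
2	Glu	EC	UNKNOWN
3	Gln	EC	UNKNOWN
4	Val	EC	UNKNOWN
5	Leu	EC	UNKNOWN
6	Gln	EC	UNKNOWN
7	Val	EC	UNKNOWN
8	Leu	EC	UNKNOWN
9	Gln	EC	UNKNOWN
10	Ser	EC	UNKNOWN
11	Val	EC	UNKNOWN
12	Leu	LCL	.
13	Ser	LCL	.
14	Ile	EC	UNKNOWN
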