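residue_class	n_D	n_L
Leu	2	2
Glx	4	0
Val	2	1
Ser	2	0
Ile	0	1
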