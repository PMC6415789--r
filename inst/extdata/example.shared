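label	Group	numOtus	Otu001	Otu002	Otu003	Otu004
0.03	starch_C12_light	4	120	340	20	5
0.03	starch_C12_heavy	4	15	30	260	2
0.03	starch_C13_light	4	120	360	15	4
0.03	starch_C13_heavy	4	190	25	240	1
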