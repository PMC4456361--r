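proband	genotype	gender	audiometric_configuration	age_at_onset	right_500	right_1000	right_2000	right_4000	right_8000	left_500	left_1000	left_2000	left_4000	left_8000	pta_right	pta_left	level	family_history
NS110	[c.107T>C]/[c.79G>A;c.341A>G]	F	Flat	<1	100	105	110	120	135	95	100	105	115	125	114	108	Profound	No
NS063	[c.235delC;c.79G>A;c.341A>G]/[c.127G>T]	M	Flat	<1	100	105	115	120	135	100	105	110	120	130	115	113	Profound	Yes
YQ054	[c.187G>T]/[c.79G>A;c.341A>G]	F	Flat	2	95	100	105	115	130	95	100	110	115	130	109	110	Profound	No
WL111	[c.293G>C]/[c.109G>A]	F	Flat	<1	90	100	105	115	130	95	105	110	120	130	108	112	Profound	Yes
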