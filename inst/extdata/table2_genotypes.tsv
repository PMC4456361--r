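genotype	mild	moderate	severe	profound	total
[c.235delC]/[c.235delC]	1	2	23	82	108
[c.235delC;c.478G>A]/[c.235delC]	0	0	0	1	1
[c.235delC;c.478G>A]/[c.235delC;c.478G>A]	0	0	0	1	1
[c.299_300delAT]/[c.299_300delAT]	0	1	0	5	6
[c.109G>A]/[c.109G>A]	5	13	9	7	34
[c.79G>A;c.109G>A;c.341A>G]/[c.109G>A]	0	2	0	1	3
[c.235delC]/[c.35insG]	0	0	0	2	2
[c.235delC]/[c.35delG]	0	0	0	1	1
[c.235delC]/[c.35G>T;c.79G>A;c.341A>G]	0	0	1	0	1
[c.235delC]/[c.127G>T;c.79G>A;c.341A>G]	0	0	0	1	1
[c.235delC]/[c.139G>T]	0	0	0	1	1
[c.235delC]/[c.176_191del16]	0	1	2	4	7
[c.235delC]/[c.299_300delAT]	0	0	4	15	19
[c.235delC;c.79G>A]/[c.299_300delAT]	0	0	0	1	1
[c.235delC;c.79G>A]/[c.439G>A]	0	1	0	1	2
[c.235delC]/[c.512_513insAACG]	0	2	1	3	6
[c.299_300delAT]/[c.139G>T]	0	0	0	1	1
[c.299_300delAT]/[c.176_191del16]	0	0	0	5	5
[c.299_300delAT]/[c.512_513insAACG]	0	0	0	1	1
[c.235delC]/[c.109G>A]	2	1	1	1	5
[c.176_191del16]/[c.109G>A]	0	0	0	2	2
[c.283G>A]/[c.109G>A]	0	0	0	1	1
[c.283G>A;c.79G>A;c.341A>G]/[c.109G>A]	0	0	1	0	1
[c.293G>C]/[c.109G>A]	0	0	0	1	1
[c.299_300delAT]/[c.109G>A]	0	1	0	2	3
[c.427C>T]/[c.109G>A]	0	0	1	1	2
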