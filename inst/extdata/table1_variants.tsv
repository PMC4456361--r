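variant	protein_label	category	dbsnp	ci_percent	case_freq	control_freq	polyphen	sift	evidence_flag	characterization
c.35insG	G12GfsX36	frameshift		NA	0.09	0			none	Pathogenic
c.35delG	G12VfsX2	frameshift	rs80338939	NA	0.09	0			none	Pathogenic
c.176_191del16	G59AfsX18	frameshift		NA	0.75	0			none	Pathogenic
c.235delC	L79CfsX3	frameshift	rs80338943	NA	13.96	0			none	Pathogenic
c.299_300delAT	H100RfsX14	frameshift	rs111033204	NA	2.25	0			none	Pathogenic
c.512_513insAACG	A172EfsX39	frameshift		NA	0.52	0			none	Pathogenic
c.139G>T	p.E47X	nonsense	rs104894398	100	0.09	0			none	Pathogenic
c.11G>A	p.G4D	missense	rs111033222	56.52	0.33	0	Benign	Tolerated	none	Polymorphism
c.35G>T	p.G12V	missense	rs1801002	100	0.05	0	Damaging	Damaging	known_pathogenic	Pathogenic
c.79G>A	p.V27I	missense	rs2274084	100	25.21	22.91	Damaging	Tolerated	none	Polymorphism
c.88A>G	p.I30V	missense	rs374625633	100	0.14	0	Benign	Tolerated	benign_in_other_controls	Polymorphism
c.107T>C	p.L36P	missense		100	0.05	0	Damaging	Damaging	none	Putative pathogenic
c.109G>A	p.V37I	missense	rs72474224	100	8.86	4.93	Damaging	Tolerated	known_pathogenic	Pathogenic
c.127G>T	p.V43L	missense		100	0.05	0	Damaging	Damaging	none	Putative pathogenic
c.187G>T	p.V63L	missense		100	0.05	0	Damaging	Damaging	none	Putative pathogenic
c.283G>A	p.V95M	missense	rs111033299	91.30	0.09	0	Damaging	Damaging	known_pathogenic	Pathogenic
c.293G>C	p.R98P	missense		78.26	0.05	0	Damaging	Damaging	none	Putative pathogenic
c.341A>G	p.E114G	missense	rs2274083	91.30	19.07	15.02	Benign	Tolerated	none	Polymorphism
c.368C>A	p.T123N	missense	rs111033188	39.13	0.23	0	Benign	Tolerated	none	Polymorphism
c.427C>T	p.R143W	missense	rs80338948	100	0.09	0	Damaging	Damaging	known_pathogenic	Pathogenic
c.439G>A	p.E147K	missense		100	0.09	0	Damaging	Damaging	known_pathogenic	Pathogenic
c.478G>A	p.G160S	missense	rs34988750	100	0.33	0	Damaging	Tolerated	benign_in_other_controls	Polymorphism
c.608T>C	p.I203T	missense	rs76838169	95.65	0.14	0	Damaging	Damaging	benign_in_other_controls	Polymorphism
c.81C>T	p.V27	silent		100	0.05	0			none	Polymorphism
c.444C>T	p.A148	silent		100	0.05	0			none	Polymorphism
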