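gene	evs	gonl	exac	effect	polyphen_score	polyphen_class	sift_score	sift_class	cond_nt	cond_aa
GRINA	1/13005	0	0/121000	NS	1	probably_damaging	0	deleterious	highly	highly
OR1J1	0	0	1/120930	NS	0.001	benign	0.56	tolerated	weakly	highly
RABEPK	11/12995	2/996	36/120704	NS	1	probably_damaging	0	deleterious	highly	highly
DEPDC7	0	0	0/120000	NS	0.896	possibly_damaging	0.07	tolerated	moderately	moderately
MAML2	1/12217	0	50/119130	NS	0.998	probably_damaging	0.06	tolerated	moderately	highly
OR8D4	6/12996	1/996	102/121352	NS	0	benign	0	deleterious	weakly	weakly
DDX25	1/12537	1/996	3/76840	NS	0	benign	0.49	tolerated	weakly	highly
CACNA2D4	0	0	3/120548	SS	undef	undef	undef	undef	na	na
TMED3	0	0	0/121000	NS	0.773	possibly_damaging	0.06	tolerated	moderately	highly
MYO15A	17/12365	4/996	199/119810	NS	0.999	probably_damaging	undef	undef	weakly	highly
STAU1	3/13003	0	16/121402	NS	0.911	possibly_damaging	0.33	tolerated	weakly	highly
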