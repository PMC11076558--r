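ConceptA	GlossA	ConceptB	GlossB	Contiguity	Function	Shape	Source
1277	hand	1673	arm	1	1	0	attested
1256	head	1371	knee	0	0	1	attested
1297	leg	1301	foot	1	1	0	synthetic
1510	chin	798	jaw	1	0	0	synthetic
1402	breast	796	nipple	1	0	0	synthetic
1303	finger	1389	toe	0	1	1	synthetic
1402	breast	1592	chest	1	0	0	synthetic
478	lip	674	mouth	1	1	0	synthetic
1173	eyebrow	1540	eyelash	1	0	1	synthetic
1277	hand	1303	finger	1	1	0	synthetic
123	forehead	1560	face	1	0	0	synthetic
980	heel	981	elbow	0	0	1	synthetic
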