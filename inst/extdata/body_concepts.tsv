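ID	Gloss	Domain
1402	breast	body
834	buttocks	body
1173	eyebrow	body
1301	foot	body
980	heel	body
1371	knee	body
803	ankle	body
1673	arm	body
1291	back	body
1251	belly	body
1730	cheek	body
1592	chest	body
1510	chin	body
1247	ear	body
981	elbow	body
1248	eye	body
1540	eyelash	body
1560	face	body
1303	finger	body
123	forehead	body
1277	hand	body
1256	head	body
1745	hip	body
798	jaw	body
1297	leg	body
478	lip	body
674	mouth	body
1838	navel	body
1333	neck	body
796	nipple	body
1221	nose	body
1482	shoulder	body
1389	toe	body
1205	tongue	body
1380	tooth	body
799	wrist	body
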