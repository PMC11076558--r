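ID	Gloss	Region
1173	eyebrow	head
1730	cheek	head
1510	chin	head
1247	ear	head
1248	eye	head
1540	eyelash	head
1560	face	head
123	forehead	head
1256	head	head
798	jaw	head
478	lip	head
674	mouth	head
1333	neck	head
1221	nose	head
1205	tongue	head
1380	tooth	head
1673	arm	upper limb
981	elbow	upper limb
1303	finger	upper limb
1277	hand	upper limb
1482	shoulder	upper limb
799	wrist	upper limb
1291	back	trunk
1251	belly	trunk
1402	breast	trunk
834	buttocks	trunk
1592	chest	trunk
1745	hip	trunk
1838	navel	trunk
796	nipple	trunk
803	ankle	lower limb
1301	foot	lower limb
980	heel	lower limb
1371	knee	lower limb
1297	leg	lower limb
1389	toe	lower limb
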