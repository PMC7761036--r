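family	activity	category	VPI-5482	CMU13	CMU108	ATCC8483	CMU19	CMU33	CMU36	CMU103
GH28	galacturonases	cellulose/pectin-active	10	10	10	14	15	15	0	0
GH95	alpha-L-fucosidase	cellulose/pectin-active	5	5	5	7	9	9	4	4
GH88	beta-glucouronyl hydrolase	cellulose/pectin-active	4	3	3	8	6	6	1	1
GH5	cellulase	cellulose/pectin-active	0	1	1	5	7	7	1	1
GH53	endo-1,4-beta-galactanase	cellulose/pectin-active	1	1	1	1	2	2	0	0
GH10	endo-1,4-beta-xylanase	cellulose/pectin-active	0	0	0	7	3	3	0	0
GH9	endoglucanase	cellulose/pectin-active	0	0	0	1	1	1	0	0
GH11	xylanase	cellulose/pectin-active	0	0	0	0	0	0	0	0
GH12	endoglucanase & xyloglucan hydrolysis	cellulose/pectin-active	0	0	0	0	0	0	0	0
GH26	beta-mannanase & xylanase	cellulose/pectin-active	0	0	0	3	0	0	2	2
GH44	endoglucanase	cellulose/pectin-active	0	0	0	0	0	0	0	0
GH45	endoglucanase	cellulose/pectin-active	0	0	0	0	0	0	0	0
GH48	endo-processive cellulases	cellulose/pectin-active	0	0	0	0	0	0	0	0
GH6	endoglucanase	cellulose/pectin-active	0	0	0	0	0	0	0	0
GH7	endoglucanase	cellulose/pectin-active	0	0	0	0	0	0	0	0
GH8	endo-xylanases	cellulose/pectin-active	0	0	0	0	0	0	0	0
GH16	xyloglucanases & xyloglycosyltransferases	cell wall elongation	3	4	4	4	7	7	4	4
GH74	endoglucanases & xyloglucanases	cell wall elongation	0	1	1	0	0	0	1	1
GH17	1,3-beta-glucosidases	cell wall elongation	0	0	0	0	0	0	0	0
GH81	1,3-beta-glucanase	cell wall elongation	0	0	0	0	0	0	0	0
GH78	alpha-L-rhamnosidase	debranching	6	9	9	8	9	9	2	2
GH106	alpha-L-rhamnosidase	debranching	3	4	4	4	4	4	0	0
GH51	alpha-L-arabinofuranosidase	debranching	4	4	4	4	4	4	2	2
GH23	peptidoglycan lyase	debranching	3	4	3	3	3	3	3	3
GH33	trans-sialidase	debranching	2	2	2	5	5	5	4	4
GH146	beta-L-arabinofuranosidase	debranching	3	2	2	3	3	3	0	0
GH27	alpha-galactosidase	debranching	5	2	2	3	2	2	2	2
GH77	4-alpha-glucanotransferase	debranching	1	1	1	1	1	1	1	1
GH84	N-acetyl beta-glucosaminidase	debranching	1	1	1	0	0	0	1	1
GH67	alpha-glucuronidase	debranching	1	0	0	2	2	2	0	0
GH103	peptidoglycan lytic transglycosylase	debranching	0	0	0	0	0	0	0	0
GH54	alpha-L-arabinofuranosidase	debranching	0	0	0	0	0	0	0	0
GH62	alpha-L-arabinofuranosidase	debranching	0	0	0	0	0	0	0	0
GH2	beta-galactosidases and other beta-linked dimers	oligosaccharide-degrading	32	34	34	37	32	32	15	15
GH43	arabinases & xylosidases	oligosaccharide-degrading	34	33	33	35	39	39	10	10
GH92	alpha-1,2-mannosidase	oligosaccharide-degrading	23	26	26	18	20	20	8	8
GH20	beta-hexosaminidase	oligosaccharide-degrading	14	13	13	13	11	11	11	11
GH3	mainly beta-glucosidases	oligosaccharide-degrading	10	11	11	21	23	23	10	10
GH105	unsaturated rhamnogalacturonyl hydrolase	oligosaccharide-degrading	7	9	9	12	15	15	0	0
GH18	chitinase	oligosaccharide-degrading	12	9	9	8	10	10	2	2
GH97	glucoamylase, alpha-glucosidase, alpha-galactosidase	oligosaccharide-degrading	10	9	9	12	9	9	4	4
GH29	alpha-L-fucosidase	oligosaccharide-degrading	9	9	9	7	5	5	9	9
GH130	beta-1,4-mannosylglucose phosphorylase	oligosaccharide-degrading	4	6	6	8	6	6	2	2
GH31	alpha-glucosidase	oligosaccharide-degrading	6	6	6	12	6	6	4	4
GH35	beta-galactosidase	oligosaccharide-degrading	3	4	4	2	5	5	3	3
GH32	invertase, endo-inulinase	oligosaccharide-degrading	4	4	4	2	3	3	2	2
GH38	alpha-mannosidase	oligosaccharide-degrading	2	4	4	1	1	1	1	1
GH127	beta-L-arabinofuranosidase	oligosaccharide-degrading	3	3	3	1	4	4	5	5
GH13	alpha-amylase	oligosaccharide-degrading	8	2	2	5	2	2	2	2
GH141	alpha-L-fucosidase, xylanase	oligosaccharide-degrading	2	2	2	2	2	2	1	1
GH27	alpha-galactosidase	oligosaccharide-degrading	5	2	2	3	2	2	2	2
GH137	beta-L-arabinofuranosidase	oligosaccharide-degrading	1	2	2	1	1	1	1	1
GH42	beta-galactosidase	oligosaccharide-degrading	1	1	1	1	3	3	0	0
GH138	alpha-galacturonidase	oligosaccharide-degrading	1	1	1	1	1	1	0	0
GH139	alpha-2-O-Me-L-fucosidase	oligosaccharide-degrading	1	1	1	1	1	1	0	0
GH142	beta-L-arabinofuranosidase	oligosaccharide-degrading	1	1	1	1	1	1	1	1
GH143	2-keto-3-deoxy-D-lyxo-heptulosaric acid hydrolase	oligosaccharide-degrading	1	1	1	1	1	1	0	0
GH57	alpha-amylase	oligosaccharide-degrading	1	1	1	1	1	1	1	1
GH147	beta-galactosidase	oligosaccharide-degrading	0	0	0	1	2	2	0	0
GH1	beta-glucosidase and many other beta-linked dimers	oligosaccharide-degrading	0	0	0	0	0	0	0	0
GH39	beta-xylosidase	oligosaccharide-degrading	0	0	0	0	0	0	0	0
GH52	beta-xylosidase	oligosaccharide-degrading	0	0	0	0	0	0	0	0
GH94	cellobiose phosphorylase	oligosaccharide-degrading	0	0	0	0	0	0	0	0
PL22	oligogalacturonate/oligogalacturonide lyase	polysaccharide lyases	0	3	3	0	3	3	4	4
PL9	pectate lyase	polysaccharide lyases	2	2	2	3	1	1	0	0
PL10	pectate lyase	polysaccharide lyases	1	1	1	1	1	1	0	0
PL26	rhamnogalacturonan exolyase	polysaccharide lyases	1	1	1	1	1	1	0	0
PL1	pectate lyase	polysaccharide lyases	5	0	0	9	0	0	0	0
PL2	pectate lyase	polysaccharide lyases	0	0	0	0	0	0	0	0
PL3	pectate lyase	polysaccharide lyases	0	0	0	0	0	0	0	0
PL4	rhamnogalacturonan endolyase	polysaccharide lyases	0	0	0	0	0	0	0	0
CE6	acetyl xylan esterase	carbohydrate esterases	1	11	11	3	17	17	3	3
CE12	pectin acetylesterase	carbohydrate esterases	2	5	5	8	7	7	0	0
CE4	chitin deacetylase	carbohydrate esterases	1	4	4	2	5	5	2	2
CE8	pectin methylesterase	carbohydrate esterases	2	2	2	6	6	6	0	0
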