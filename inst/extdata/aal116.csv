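"index","name","abbrev","hemisphere","division"
1,"Precentral gyrus","PreCG.L","L","cerebrum"
2,"Precentral gyrus","PreCG.R","R","cerebrum"
3,"Superior frontal gyrus, dorsolateral","SFGdor.L","L","cerebrum"
4,"Superior frontal gyrus, dorsolateral","SFGdor.R","R","cerebrum"
5,"Superior frontal gyrus, orbital part","ORBsup.L","L","cerebrum"
6,"Superior frontal gyrus, orbital part","ORBsup.R","R","cerebrum"
7,"Middle frontal gyrus","MFG.L","L","cerebrum"
8,"Middle frontal gyrus","MFG.R","R","cerebrum"
9,"Middle frontal gyrus, orbital part","ORBmid.L","L","cerebrum"
10,"Middle frontal gyrus, orbital part","ORBmid.R","R","cerebrum"
11,"Inferior frontal gyrus, opercular part","IFGoperc.L","L","cerebrum"
12,"Inferior frontal gyrus, opercular part","IFGoperc.R","R","cerebrum"
13,"Inferior frontal gyrus, triangular part","IFGtriang.L","L","cerebrum"
14,"Inferior frontal gyrus, triangular part","IFGtriang.R","R","cerebrum"
15,"Inferior frontal gyrus, orbital part","ORBinf.L","L","cerebrum"
16,"Inferior frontal gyrus, orbital part","ORBinf.R","R","cerebrum"
17,"Rolandic operculum","ROL.L","L","cerebrum"
18,"Rolandic operculum","ROL.R","R","cerebrum"
19,"Supplementary motor area","SMA.L","L","cerebrum"
20,"Supplementary motor area","SMA.R","R","cerebrum"
21,"Olfactory cortex","OLF.L","L","cerebrum"
22,"Olfactory cortex","OLF.R","R","cerebrum"
23,"Superior frontal gyrus, medial","SFGmed.L","L","cerebrum"
24,"Superior frontal gyrus, medial","SFGmed.R","R","cerebrum"
25,"Superior frontal gyrus, medial orbital","ORBsupmed.L","L","cerebrum"
26,"Superior frontal gyrus, medial orbital","ORBsupmed.R","R","cerebrum"
27,"Gyrus rectus","REC.L","L","cerebrum"
28,"Gyrus rectus","REC.R","R","cerebrum"
29,"Insula","INS.L","L","cerebrum"
30,"Insula","INS.R","R","cerebrum"
31,"Anterior cingulate and paracingulate gyri","ACG.L","L","cerebrum"
32,"Anterior cingulate and paracingulate gyri","ACG.R","R","cerebrum"
33,"Median cingulate and paracingulate gyri","DCG.L","L","cerebrum"
34,"Median cingulate and paracingulate gyri","DCG.R","R","cerebrum"
35,"Posterior cingulate gyrus","PCG.L","L","cerebrum"
36,"Posterior cingulate gyrus","PCG.R","R","cerebrum"
37,"Hippocampus","HIP.L","L","cerebrum"
38,"Hippocampus","HIP.R","R","cerebrum"
39,"Parahippocampal gyrus","PHG.L","L","cerebrum"
40,"Parahippocampal gyrus","PHG.R","R","cerebrum"
41,"Amygdala","AMYG.L","L","cerebrum"
42,"Amygdala","AMYG.R","R","cerebrum"
43,"Calcarine fissure and surrounding cortex","CAL.L","L","cerebrum"
44,"Calcarine fissure and surrounding cortex","CAL.R","R","cerebrum"
45,"Cuneus","CUN.L","L","cerebrum"
46,"Cuneus","CUN.R","R","cerebrum"
47,"Lingual gyrus","LING.L","L","cerebrum"
48,"Lingual gyrus","LING.R","R","cerebrum"
49,"Superior occipital gyrus","SOG.L","L","cerebrum"
50,"Superior occipital gyrus","SOG.R","R","cerebrum"
51,"Middle occipital gyrus","MOG.L","L","cerebrum"
52,"Middle occipital gyrus","MOG.R","R","cerebrum"
53,"Inferior occipital gyrus","IOG.L","L","cerebrum"
54,"Inferior occipital gyrus","IOG.R","R","cerebrum"
55,"Fusiform gyrus","FFG.L","L","cerebrum"
56,"Fusiform gyrus","FFG.R","R","cerebrum"
57,"Postcentral gyrus","PoCG.L","L","cerebrum"
58,"Postcentral gyrus","PoCG.R","R","cerebrum"
59,"Superior parietal gyrus","SPG.L","L","cerebrum"
60,"Superior parietal gyrus","SPG.R","R","cerebrum"
61,"Inferior parietal gyrus","IPL.L","L","cerebrum"
62,"Inferior parietal gyrus","IPL.R","R","cerebrum"
63,"Supramarginal gyrus","SMG.L","L","cerebrum"
64,"Supramarginal gyrus","SMG.R","R","cerebrum"
65,"Angular gyrus","ANG.L","L","cerebrum"
66,"Angular gyrus","ANG.R","R","cerebrum"
67,"Precuneus","PCUN.L","L","cerebrum"
68,"Precuneus","PCUN.R","R","cerebrum"
69,"Paracentral lobule","PCL.L","L","cerebrum"
70,"Paracentral lobule","PCL.R","R","cerebrum"
71,"Caudate nucleus","CAU.L","L","cerebrum"
72,"Caudate nucleus","CAU.R","R","cerebrum"
73,"Putamen","PUT.L","L","cerebrum"
74,"Putamen","PUT.R","R","cerebrum"
75,"Pallidum","PAL.L","L","cerebrum"
76,"Pallidum","PAL.R","R","cerebrum"
77,"Thalamus","THA.L","L","cerebrum"
78,"Thalamus","THA.R","R","cerebrum"
79,"Heschl gyrus","HES.L","L","cerebrum"
80,"Heschl gyrus","HES.R","R","cerebrum"
81,"Superior temporal gyrus","STG.L","L","cerebrum"
82,"Superior temporal gyrus","STG.R","R","cerebrum"
83,"Temporal pole: superior temporal gyrus","TPOsup.L","L","cerebrum"
84,"Temporal pole: superior temporal gyrus","TPOsup.R","R","cerebrum"
85,"Middle temporal gyrus","MTG.L","L","cerebrum"
86,"Middle temporal gyrus","MTG.R","R","cerebrum"
87,"Temporal pole: middle temporal gyrus","TPOmid.L","L","cerebrum"
88,"Temporal pole: middle temporal gyrus","TPOmid.R","R","cerebrum"
89,"Inferior temporal gyrus","ITG.L","L","cerebrum"
90,"Inferior temporal gyrus","ITG.R","R","cerebrum"
91,"Cerebellum crus 1","CRBLCrus1.L","L","cerebellum"
92,"Cerebellum crus 1","CRBLCrus1.R","R","cerebellum"
93,"Cerebellum crus 2","CRBLCrus2.L","L","cerebellum"
94,"Cerebellum crus 2","CRBLCrus2.R","R","cerebellum"
95,"Cerebellum 3","CRBL3.L","L","cerebellum"
96,"Cerebellum 3","CRBL3.R","R","cerebellum"
97,"Cerebellum 4 and 5","CRBL45.L","L","cerebellum"
98,"Cerebellum 4 and 5","CRBL45.R","R","cerebellum"
99,"Cerebellum 6","CRBL6.L","L","cerebellum"
100,"Cerebellum 6","CRBL6.R","R","cerebellum"
101,"Cerebellum 7b","CRBL7b.L","L","cerebellum"
102,"Cerebellum 7b","CRBL7b.R","R","cerebellum"
103,"Cerebellum 8","CRBL8.L","L","cerebellum"
104,"Cerebellum 8","CRBL8.R","R","cerebellum"
105,"Cerebellum 9","CRBL9.L","L","cerebellum"
106,"Cerebellum 9","CRBL9.R","R","cerebellum"
107,"Cerebellum 10","CRBL10.L","L","cerebellum"
108,"Cerebellum 10","CRBL10.R","R","cerebellum"
109,"Vermis 1 and 2","Vermis12","M","cerebellum"
110,"Vermis 3","Vermis3","M","cerebellum"
111,"Vermis 4 and 5","Vermis45","M","cerebellum"
112,"Vermis 6","Vermis6","M","cerebellum"
113,"Vermis 7","Vermis7","M","cerebellum"
114,"Vermis 8","Vermis8","M","cerebellum"
115,"Vermis 9","Vermis9","M","cerebellum"
116,"Vermis 10","Vermis10","M","cerebellum"
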