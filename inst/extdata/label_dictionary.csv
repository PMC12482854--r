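"id","name","tissue"
1,"CSF","CSF"
2,"3rd Ventricle","CSF"
3,"4th Ventricle","CSF"
4,"Lateral Ventricles","CSF"
5,"Left Inf Lat Vent","CSF"
6,"Right Inf Lat Vent","CSF"
7,"Left Cerebral White Matter","WM"
8,"Right Cerebral White Matter","WM"
9,"Left Cerebellum White Matter","WM"
10,"Right Cerebellum White Matter","WM"
11,"Left Accumbens Area","GM"
12,"Left Amygdala","GM"
13,"Left Caudate","GM"
14,"Left Cerebellum Exterior","GM"
15,"Left Hippocampus","GM"
16,"Left Pallidum","GM"
17,"Left Putamen","GM"
18,"Left Thalamus Proper","GM"
19,"Left Ventral DC","GM"
20,"Left Basal Forebrain","GM"
21,"Right Accumbens Area","GM"
22,"Right Amygdala","GM"
23,"Right Caudate","GM"
24,"Right Cerebellum Exterior","GM"
25,"Right Hippocampus","GM"
26,"Right Pallidum","GM"
27,"Right Putamen","GM"
28,"Right Thalamus Proper","GM"
29,"Right Ventral DC","GM"
30,"Right Basal Forebrain","GM"
31,"Brain Stem","GM"
32,"Cerebellar Vermal Lobules I-V","GM"
33,"Cerebellar Vermal Lobules VI-VII","GM"
34,"Cerebellar Vermal Lobules VIII-X","GM"
35,"Left ACgG anterior cingulate gyrus","GM"
36,"Left AIns anterior insula","GM"
37,"Left AOrG anterior orbital gyrus","GM"
38,"Left AnG angular gyrus","GM"
39,"Left Calc calcarine cortex","GM"
40,"Left CO central operculum","GM"
41,"Left Cun cuneus","GM"
42,"Left Ent entorhinal area","GM"
43,"Left FO frontal operculum","GM"
44,"Left FRP frontal pole","GM"
45,"Left FuG fusiform gyrus","GM"
46,"Left GRe gyrus rectus","GM"
47,"Left IOG inferior occipital gyrus","GM"
48,"Left ITG inferior temporal gyrus","GM"
49,"Left LiG lingual gyrus","GM"
50,"Left LOrG lateral orbital gyrus","GM"
51,"Left MCgG middle cingulate gyrus","GM"
52,"Left MFC medial frontal cortex","GM"
53,"Left MFG middle frontal gyrus","GM"
54,"Left MOG middle occipital gyrus","GM"
55,"Left MOrG medial orbital gyrus","GM"
56,"Left MPoG postcentral gyrus medial segment","GM"
57,"Left MPrG precentral gyrus medial segment","GM"
58,"Left MSFG superior frontal gyrus medial segment","GM"
59,"Left MTG middle temporal gyrus","GM"
60,"Left OCP occipital pole","GM"
61,"Left OFuG occipital fusiform gyrus","GM"
62,"Left OpIFG opercular part of the inferior frontal gyrus","GM"
63,"Left OrIFG orbital part of the inferior frontal gyrus","GM"
64,"Left PCgG posterior cingulate gyrus","GM"
65,"Left PCu precuneus","GM"
66,"Left PHG parahippocampal gyrus","GM"
67,"Left PIns posterior insula","GM"
68,"Left PO parietal operculum","GM"
69,"Left PoG postcentral gyrus","GM"
70,"Left POrG posterior orbital gyrus","GM"
71,"Left PP planum polare","GM"
72,"Left PrG precentral gyrus","GM"
73,"Left PT planum temporale","GM"
74,"Left SCA subcallosal area","GM"
75,"Left SFG superior frontal gyrus","GM"
76,"Left SMC supplementary motor cortex","GM"
77,"Left SMG supramarginal gyrus","GM"
78,"Left SOG superior occipital gyrus","GM"
79,"Left SPL superior parietal lobule","GM"
80,"Left STG superior temporal gyrus","GM"
81,"Left TMP temporal pole","GM"
82,"Left TrIFG triangular part of the inferior frontal gyrus","GM"
83,"Left TTG transverse temporal gyrus","GM"
84,"Right ACgG anterior cingulate gyrus","GM"
85,"Right AIns anterior insula","GM"
86,"Right AOrG anterior orbital gyrus","GM"
87,"Right AnG angular gyrus","GM"
88,"Right Calc calcarine cortex","GM"
89,"Right CO central operculum","GM"
90,"Right Cun cuneus","GM"
91,"Right Ent entorhinal area","GM"
92,"Right FO frontal operculum","GM"
93,"Right FRP frontal pole","GM"
94,"Right FuG fusiform gyrus","GM"
95,"Right GRe gyrus rectus","GM"
96,"Right IOG inferior occipital gyrus","GM"
97,"Right ITG inferior temporal gyrus","GM"
98,"Right LiG lingual gyrus","GM"
99,"Right LOrG lateral orbital gyrus","GM"
100,"Right MCgG middle cingulate gyrus","GM"
101,"Right MFC medial frontal cortex","GM"
102,"Right MFG middle frontal gyrus","GM"
103,"Right MOG middle occipital gyrus","GM"
104,"Right MOrG medial orbital gyrus","GM"
105,"Right MPoG postcentral gyrus medial segment","GM"
106,"Right MPrG precentral gyrus medial segment","GM"
107,"Right MSFG superior frontal gyrus medial segment","GM"
108,"Right MTG middle temporal gyrus","GM"
109,"Right OCP occipital pole","GM"
110,"Right OFuG occipital fusiform gyrus","GM"
111,"Right OpIFG opercular part of the inferior frontal gyrus","GM"
112,"Right OrIFG orbital part of the inferior frontal gyrus","GM"
113,"Right PCgG posterior cingulate gyrus","GM"
114,"Right PCu precuneus","GM"
115,"Right PHG parahippocampal gyrus","GM"
116,"Right PIns posterior insula","GM"
117,"Right PO parietal operculum","GM"
118,"Right PoG postcentral gyrus","GM"
119,"Right POrG posterior orbital gyrus","GM"
120,"Right PP planum polare","GM"
121,"Right PrG precentral gyrus","GM"
122,"Right PT planum temporale","GM"
123,"Right SCA subcallosal area","GM"
124,"Right SFG superior frontal gyrus","GM"
125,"Right SMC supplementary motor cortex","GM"
126,"Right SMG supramarginal gyrus","GM"
127,"Right SOG superior occipital gyrus","GM"
128,"Right SPL superior parietal lobule","GM"
129,"Right STG superior temporal gyrus","GM"
130,"Right TMP temporal pole","GM"
131,"Right TrIFG triangular part of the inferior frontal gyrus","GM"
132,"Right TTG transverse temporal gyrus","GM"
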