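index	name	hemisphere
1	precentral	L
2	precentral	R
7	middle_frontal	L
8	middle_frontal	R
11	inferior_frontal_opercular	L
12	inferior_frontal_opercular	R
13	inferior_frontal_triangular	L
14	inferior_frontal_triangular	R
19	supplementary_motor	L
20	supplementary_motor	R
49	superior_occipital	L
50	superior_occipital	R
51	middle_occipital	L
52	middle_occipital	R
53	inferior_occipital	L
54	inferior_occipital	R
55	fusiform	L
56	fusiform	R
61	inferior_parietal	L
62	inferior_parietal	R
63	supramarginal	L
64	supramarginal	R
65	angular	L
66	angular	R
81	superior_temporal	L
82	superior_temporal	R
83	superior_temporal_pole	L
84	superior_temporal_pole	R
85	middle_temporal	L
86	middle_temporal	R
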