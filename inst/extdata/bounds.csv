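id,name,group,organ,species,unit,min,max
1,Kp_lung_CPT-11,Kp,lung,CPT-11,-,0.1,10
2,Kp_lung_SN-38,Kp,lung,SN-38,-,0.1,10
3,Kp_lung_SN-38G,Kp,lung,SN-38G,-,0.1,10
4,Kp_lung_NPC,Kp,lung,NPC,-,0.1,10
5,Kp_lung_APC,Kp,lung,APC,-,0.1,10
6,Kp_heart_CPT-11,Kp,heart,CPT-11,-,0.1,10
7,Kp_heart_SN-38,Kp,heart,SN-38,-,0.1,10
8,Kp_heart_SN-38G,Kp,heart,SN-38G,-,0.1,10
9,Kp_heart_NPC,Kp,heart,NPC,-,0.1,10
10,Kp_heart_APC,Kp,heart,APC,-,0.1,10
11,Kp_brain_CPT-11,Kp,brain,CPT-11,-,0.1,10
12,Kp_brain_SN-38,Kp,brain,SN-38,-,0.1,10
13,Kp_brain_SN-38G,Kp,brain,SN-38G,-,0.1,10
14,Kp_brain_NPC,Kp,brain,NPC,-,0.1,10
15,Kp_brain_APC,Kp,brain,APC,-,0.1,10
16,Kp_muscle_CPT-11,Kp,muscle,CPT-11,-,0.1,10
17,Kp_muscle_SN-38,Kp,muscle,SN-38,-,0.1,10
18,Kp_muscle_SN-38G,Kp,muscle,SN-38G,-,0.1,10
19,Kp_muscle_NPC,Kp,muscle,NPC,-,0.1,10
20,Kp_muscle_APC,Kp,muscle,APC,-,0.1,10
21,Kp_adipose_CPT-11,Kp,adipose,CPT-11,-,0.1,10
22,Kp_adipose_SN-38,Kp,adipose,SN-38,-,0.1,10
23,Kp_adipose_SN-38G,Kp,adipose,SN-38G,-,0.1,10
24,Kp_adipose_NPC,Kp,adipose,NPC,-,0.1,10
25,Kp_adipose_APC,Kp,adipose,APC,-,0.1,10
26,Kp_skin_CPT-11,Kp,skin,CPT-11,-,0.1,10
27,Kp_skin_SN-38,Kp,skin,SN-38,-,0.1,10
28,Kp_skin_SN-38G,Kp,skin,SN-38G,-,0.1,10
29,Kp_skin_NPC,Kp,skin,NPC,-,0.1,10
30,Kp_skin_APC,Kp,skin,APC,-,0.1,10
31,Kp_bone_CPT-11,Kp,bone,CPT-11,-,0.1,10
32,Kp_bone_SN-38,Kp,bone,SN-38,-,0.1,10
33,Kp_bone_SN-38G,Kp,bone,SN-38G,-,0.1,10
34,Kp_bone_NPC,Kp,bone,NPC,-,0.1,10
35,Kp_bone_APC,Kp,bone,APC,-,0.1,10
36,Kp_kidney_CPT-11,Kp,kidney,CPT-11,-,0.1,10
37,Kp_kidney_SN-38,Kp,kidney,SN-38,-,0.1,10
38,Kp_kidney_SN-38G,Kp,kidney,SN-38G,-,0.1,10
39,Kp_kidney_NPC,Kp,kidney,NPC,-,0.1,10
40,Kp_kidney_APC,Kp,kidney,APC,-,0.1,10
41,Kp_spleen_CPT-11,Kp,spleen,CPT-11,-,0.1,10
42,Kp_spleen_SN-38,Kp,spleen,SN-38,-,0.1,10
43,Kp_spleen_SN-38G,Kp,spleen,SN-38G,-,0.1,10
44,Kp_spleen_NPC,Kp,spleen,NPC,-,0.1,10
45,Kp_spleen_APC,Kp,spleen,APC,-,0.1,10
46,Kp_pancreas_CPT-11,Kp,pancreas,CPT-11,-,0.1,10
47,Kp_pancreas_SN-38,Kp,pancreas,SN-38,-,0.1,10
48,Kp_pancreas_SN-38G,Kp,pancreas,SN-38G,-,0.1,10
49,Kp_pancreas_NPC,Kp,pancreas,NPC,-,0.1,10
50,Kp_pancreas_APC,Kp,pancreas,APC,-,0.1,10
51,Kp_stomach_CPT-11,Kp,stomach,CPT-11,-,0.1,10
52,Kp_stomach_SN-38,Kp,stomach,SN-38,-,0.1,10
53,Kp_stomach_SN-38G,Kp,stomach,SN-38G,-,0.1,10
54,Kp_stomach_NPC,Kp,stomach,NPC,-,0.1,10
55,Kp_stomach_APC,Kp,stomach,APC,-,0.1,10
56,Kp_small_intestine_CPT-11,Kp,small_intestine,CPT-11,-,0.1,10
57,Kp_small_intestine_SN-38,Kp,small_intestine,SN-38,-,0.1,10
58,Kp_small_intestine_SN-38G,Kp,small_intestine,SN-38G,-,0.1,10
59,Kp_small_intestine_NPC,Kp,small_intestine,NPC,-,0.1,10
60,Kp_small_intestine_APC,Kp,small_intestine,APC,-,0.1,10
61,Kp_large_intestine_CPT-11,Kp,large_intestine,CPT-11,-,0.1,10
62,Kp_large_intestine_SN-38,Kp,large_intestine,SN-38,-,0.1,10
63,Kp_large_intestine_SN-38G,Kp,large_intestine,SN-38G,-,0.1,10
64,Kp_large_intestine_NPC,Kp,large_intestine,NPC,-,0.1,10
65,Kp_large_intestine_APC,Kp,large_intestine,APC,-,0.1,10
66,Kp_liver_CPT-11,Kp,liver,CPT-11,-,0.1,10
67,Kp_liver_SN-38,Kp,liver,SN-38,-,0.1,10
68,Kp_liver_SN-38G,Kp,liver,SN-38G,-,0.1,10
69,Kp_liver_NPC,Kp,liver,NPC,-,0.1,10
70,Kp_liver_APC,Kp,liver,APC,-,0.1,10
71,CLr_CPT-11,CLr,NA,CPT-11,ml/min/kg,0.1,10
72,CLr_SN-38,CLr,NA,SN-38,ml/min/kg,0.01,1
73,CLr_SN-38G,CLr,NA,SN-38G,ml/min/kg,0.01,1
74,CLr_NPC,CLr,NA,NPC,ml/min/kg,0.01,1
75,CLr_APC,CLr,NA,APC,ml/min/kg,0.01,1
76,CLbile_CPT-11,CLbile,NA,CPT-11,ml/min/kg,0.1,10
77,CLbile_SN-38,CLbile,NA,SN-38,ml/min/kg,0.1,10
78,CLbile_SN-38G,CLbile,NA,SN-38G,ml/min/kg,0.1,10
79,CLbile_NPC,CLbile,NA,NPC,ml/min/kg,0.1,10
80,CLbile_APC,CLbile,NA,APC,ml/min/kg,0.1,10
81,CL_CES1,CLmet,NA,NA,ml/min/kg,0.1,10
82,CL_CES2,CLmet,NA,NA,ml/min/kg,0.1,10
83,CL_3A4_1,CLmet,NA,NA,ml/min/kg,0.1,10
84,CL_3A4_2,CLmet,NA,NA,ml/min/kg,0.1,10
85,CL_UGT,CLmet,NA,NA,ml/min/kg,0.1,10
86,kbile_CPT-11,kbile,NA,CPT-11,/min,0.001,0.1
87,kbile_SN-38,kbile,NA,SN-38,/min,0.001,0.1
88,kbile_SN-38G,kbile,NA,SN-38G,/min,0.001,0.1
89,kbile_NPC,kbile,NA,NPC,/min,0.001,0.1
90,kbile_APC,kbile,NA,APC,/min,0.001,0.1
91,ka_CPT-11,ka,NA,CPT-11,/min,1e-04,0.01
92,ka_SN-38,ka,NA,SN-38,/min,1e-04,0.01
93,ka_SN-38G,ka,NA,SN-38G,/min,1e-04,0.01
94,ka_NPC,ka,NA,NPC,/min,1e-04,0.01
95,ka_APC,ka,NA,APC,/min,1e-04,0.01
96,kLI_CPT-11,kLI,NA,CPT-11,/min,1e-04,0.01
97,kLI_SN-38,kLI,NA,SN-38,/min,1e-04,0.01
98,kLI_SN-38G,kLI,NA,SN-38G,/min,1e-04,0.01
99,kLI_NPC,kLI,NA,NPC,/min,1e-04,0.01
100,kLI_APC,kLI,NA,APC,/min,1e-04,0.01
101,kfeces_CPT-11,kfeces,NA,CPT-11,/min,1e-04,0.01
102,kfeces_SN-38,kfeces,NA,SN-38,/min,1e-04,0.01
103,kfeces_SN-38G,kfeces,NA,SN-38G,/min,1e-04,0.01
104,kfeces_NPC,kfeces,NA,NPC,/min,1e-04,0.01
105,kfeces_APC,kfeces,NA,APC,/min,1e-04,0.01
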