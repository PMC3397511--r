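compound_id,scaffold_id,r1_name,r1_smiles,r2_name,r2_smiles,confidence
1,oxazolone,Ph,c6ccccc6,H,,normal
2,oxazolone,Et,CC,H,,normal
3,oxazolone,i-Pr,C(C)C,H,,normal
4,oxazolone,t-Bu,C(C)(C)C,H,,normal
5,oxazolone,c-Pr,C6CC6,H,,normal
6,oxazolone,c-Pentyl,C6CCCC6,H,,normal
7,oxazolone,c-Heptanyl,C6CCCCCC6,H,,normal
8,oxazolone,Bn,Cc6ccccc6,H,,normal
9,oxazolone,MeOCH2CH2,CCOC,H,,normal
10,oxazolone,Benzoyl,C(=O)c6ccccc6,H,,normal
11,oxazolone,1-Naphthyl,c6cccc7ccccc67,H,,normal
12,oxazolone,H,,H,,normal
13,oxazolone,Me,C,H,,normal
14,oxazolone,Et,CC,H,,normal
15,oxazolone,n-Pr,CCC,H,,normal
16,oxazolone,c-Pr,C6CC6,H,,normal
17,aryl,4-Me,c6ccc(C)cc6,H,,normal
18,aryl,4-Cl,c6ccc(Cl)cc6,H,,normal
19,aryl,4-MeO,c6ccc(OC)cc6,H,,normal
20,aryl,4-i-Pr,c6ccc(C(C)C)cc6,H,,normal
21,aryl,4-t-Bu,c6ccc(C(C)(C)C)cc6,H,,normal
22,aryl,4-Br,c6ccc(Br)cc6,H,,normal
23,aryl,4-NO2,c6ccc([N+](=O)[O-])cc6,H,,normal
24,aryl,4-CN,c6ccc(C#N)cc6,H,,normal
25,aryl,4-BnO,c6ccc(OCc7ccccc7)cc6,H,,normal
26,aryl,4-Ac,c6ccc(C(C)=O)cc6,H,,normal
27,aryl,4-EtOC(=O)-,c6ccc(C(=O)OCC)cc6,H,,normal
28,aryl,4-NMe2,c6ccc(N(C)C)cc6,H,,normal
29,aryl,4-(Morphorin-1-yl),c6ccc(N7CCOCC7)cc6,H,,normal
30,aryl,4-AcNH-,c6ccc(NC(C)=O)cc6,H,,normal
31,aryl,4-NH2,c6ccc(N)cc6,H,,normal
32,aryl,4-BnOC(=O)NH-,c6ccc(NC(=O)OCc7ccccc7)cc6,H,,normal
33,aryl,2-Me,c6c(C)cccc6,H,,normal
34,aryl,2-Cl,c6c(Cl)cccc6,H,,normal
35,aryl,2-MeO,c6c(OC)cccc6,H,,normal
36,aryl,2-F,c6c(F)cccc6,H,,normal
37,aryl,2-MeS,c6c(SC)cccc6,H,,normal
38,aryl,3-Me,c6cc(C)ccc6,H,,normal
39,aryl,3-Cl,c6cc(Cl)ccc6,H,,normal
40,aryl,3-MeO,c6cc(OC)ccc6,H,,normal
41,aryl,"2,4-Di-MeO",c6c(OC)cc(OC)cc6,H,,normal
42,aryl,"2,4-Di-Cl",c6c(Cl)cc(Cl)cc6,H,,normal
43,aryl,"3,5-Di-Cl",c6cc(Cl)cc(Cl)c6,H,,normal
44,aryl,MeOC(=O)NH-,c6ccc(NC(=O)OC)cc6,Cl,Cl,normal
45,aryl,EtOC(=O)NH-,c6ccc(NC(=O)OCC)cc6,Cl,Cl,normal
46,aryl,n-BuOC(=O)NH-,c6ccc(NC(=O)OCCCC)cc6,Cl,Cl,normal
47,aryl,i-BuOC(=O)NH-,c6ccc(NC(=O)OCC(C)C)cc6,Cl,Cl,normal
48,aryl,t-BuOC(=O)NH-,c6ccc(NC(=O)OC(C)(C)C)cc6,Cl,Cl,normal
49,aryl,i-BuOC(=O)N(Ph)-,c6ccc(N(c7ccccc7)C(=O)OCC(C)C)cc6,Cl,Cl,normal
50,aryl,MeNHC(=O)NH-,c6ccc(NC(=O)NC)cc6,Cl,Cl,normal
51,aryl,t-BuNHC(=O)NH-,c6ccc(NC(=O)NC(C)(C)C)cc6,Cl,Cl,normal
52,aryl,t-BuOC(=O)NH-,c6ccc(NC(=O)OC(C)(C)C)cc6,Me,C,normal
53,aryl,PhOC(=O)NH-,c6ccc(NC(=O)Oc7ccccc7)cc6,Me,C,normal
54,aryl,EtOC(=O)N(Me)-,c6ccc(N(C)C(=O)OCC)cc6,Me,C,normal
55,aryl,t-BuOC(=O)O-,c6ccc(OC(=O)OC(C)(C)C)cc6,Me,C,normal
56,aryl,EtC(=O)NH-,c6ccc(NC(=O)CC)cc6,Me,C,normal
57,aryl,n-PrC(=O)NH-,c6ccc(NC(=O)CCC)cc6,Me,C,normal
58,aryl,n-BuC(=O)NH-,c6ccc(NC(=O)CCCC)cc6,Me,C,normal
59,aryl,BnC(=O)NH-,c6ccc(NC(=O)Cc7ccccc7)cc6,Me,C,normal
60,aryl,PhC(=O)NH-,c6ccc(NC(=O)c7ccccc7)cc6,Me,C,normal
61,aryl,3-NHC(=O)NH-4,c6ccc7c(c6)NC(=O)N7,H,,normal
62,aryl,3-CH2C(=O)NH-4,c6ccc7c(c6)CC(=O)N7,H,,normal
63,aryl,3-SC(=O)NH-4,c6ccc7c(c6)SC(=O)N7,H,,normal
64,aryl,3-NHC(=O)O-4,c6ccc7c(c6)NC(=O)O7,H,,normal
65,aryl,fig-R1-a,c6ccc7c(c6)NC(=O)O7,Et,CC,low
66,aryl,fig-R1-a,c6ccc7c(c6)NC(=O)O7,n-Pr,CCC,low
67,aryl,fig-R1-a,c6ccc7c(c6)NC(=O)O7,c-Pr,C8CC8,low
68,aryl,fig-R1-b,c6cc(F)c7c(c6)NC(=O)O7,n-Pr,CCC,low
69,aryl,fig-R1-b,c6cc(F)c7c(c6)NC(=O)O7,n-Bu,CCCC,low
70,aryl,fig-R1-c,c6ccc7c(c6)OC(=O)N7,c-Pr,C8CC8,low
71,aryl,fig-R1-d,c6cc(C)c7c(c6)NC(=O)O7,c-Pr,C8CC8,low
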