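"age","q"
0,0.000549848777725348
1,0.000554828968208687
2,0.000560305450124976
3,0.000566327677315792
4,0.000572950030881425
5,0.000580232309963624
6,0.000588240271384377
7,0.000597046222996944
8,0.0006067296760911
9,0.000617378062717222
10,0.000629087524382621
11,0.000641963779205001
12,0.000656123075314818
13,0.000671693239064242
14,0.000688814827449202
15,0.000707642395076258
16,0.000728345887028303
17,0.000751112170096269
18,0.000776146716076731
19,0.000803675452175634
20,0.0008339467950369
21,0.000867233886532093
22,0.000903837051219436
23,0.000944086497324692
24,0.000988345285222403
25,0.00103701258972611
26,0.00109052728504566
27,0.00114937188405484
28,0.00121407686656183
29,0.00128522543460152
30,0.00136345873640165
31,0.00144948160463876
32,0.00154406885891478
33,0.00164807222708929
34,0.00176242794521186
35,0.00188816510135115
36,0.00202641479464272
37,0.00217842018739167
38,0.00234554753512406
39,0.00252929828707715
40,0.00273132235781093
41,0.00295343267940562
42,0.00319762115311795
43,0.0034660761293982
44,0.00376120155582793
45,0.00408563794380601
46,0.00444228531665392
47,0.00483432831419062
48,0.00526526364163782
49,0.00573893006387505
50,0.00625954115938077
51,0.00683172106148244
52,0.00746054342750757
53,0.00815157388872001
54,0.00891091624509077
55,0.00974526267840481
56,0.0106619482642299
57,0.0116690100669674
58,0.0127752511014615
59,0.013990309438103
60,0.0153247327143657
61,0.0167900582922471
62,0.0183988992657113
63,0.0201650364720414
64,0.0221035165924975
65,0.0242307563367047
66,0.02656465258685
67,0.0291246982262997
68,0.0319321031859089
69,0.0350099200023285
70,0.0383831728870342
71,0.0420789889424695
72,0.0461267297211323
73,0.0505581207919852
74,0.0554073763423957
75,0.0607113150882047
76,0.0665094628742587
77,0.0728441363077801
78,0.0797605005633462
79,0.0873065931196035
80,0.095533303627181
81,0.104494298364712
82,0.114245875826082
83,0.124846737922696
84,0.136357659126215
85,0.148841033694141
86,0.162360279023661
87,0.176979071325469
88,0.192760388414049
89,0.209765333759087
90,0.228051716401589
91,0.247672363367712
92,0.268673145372057
93,0.29109070354722
94,0.314949875409607
95,0.340260833067002
96,0.367015966580041
97,0.395186571094963
98,0.424719428315766
99,0.455533411090304
100,0.487516283666983
101,0.52052191785476
102,0.554368193857415
103,0.58883589922208
104,0.62366897343341
105,0.658576460412867
106,0.693236515912666
107,0.727302759782505
108,1
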