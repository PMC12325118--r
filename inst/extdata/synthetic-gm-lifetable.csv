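"age","qx"
0,0.000529859574809555
1,0.000532847751840371
2,0.000536133716859233
3,0.00053974714491789
4,0.000543720667998349
5,0.000548090169602333
6,0.000552895108680285
7,0.000558178875817661
8,0.000563989184890645
9,0.000570378503717994
10,0.000577404527589365
11,0.0005851306999336
12,0.000593626784814782
13,0.000602969496406924
14,0.000613243191112445
15,0.000624540628545334
16,0.000636963808222979
17,0.000650624889479867
18,0.000665647202867214
19,0.000682166362113046
20,0.000700331486616745
21,0.000720306545434757
22,0.000742271834792252
23,0.000766425602344634
24,0.000792985832704707
25,0.000822192210185424
26,0.000854308276263871
27,0.000889623800988004
28,0.000928457389425374
29,0.000971159346307093
30,0.00101811482427216
31,0.00106974728358267
32,0.00112652229387189
33,0.0011889517114384
34,0.00125759826881378
35,0.00133308061684989
36,0.00141607886340678
37,0.00150734065690017
38,0.00160768786752374
39,0.00171802392391374
40,0.00183934186840495
41,0.00197273319986968
42,0.00211939757946122
43,0.00228065348142814
44,0.00245794987855874
45,0.00265287905977951
46,0.00286719068598762
47,0.00310280719936995
48,0.003361840711254
49,0.00364661150395917
50,0.00395966829315608
51,0.00430381040887429
52,0.00468211206548186
53,0.00509794890362114
54,0.00555502700012911
55,0.00605741455524589
56,0.00660957647974669
57,0.00721641211775581
58,0.00788329635359586
59,0.00861612436267978
60,0.00942136027662377
61,0.0103060900407979
62,0.0112780787475967
63,0.012345832729789
64,0.0135186666941274
65,0.0148067761644323
66,0.0162213154837239
67,0.0177744815944176
68,0.0194796037713623
69,0.0213512394213553
70,0.0234052759807972
71,0.0256590388357553
72,0.0281314050504633
73,0.0308429225148384
74,0.0338159339015743
75,0.03707470455027
76,0.040645553060165
77,0.0445569829634216
78,0.0488398133552759
79,0.0535273057623961
80,0.058655283821982
81,0.0642622415064537
82,0.070389434646793
83,0.0770809493672198
84,0.0843837397323566
85,0.0923476254164516
86,0.101025238529671
87,0.110471906885158
88,0.120745458981912
89,0.131905933850496
90,0.14401517672396
91,0.157136299351246
92,0.171332981802999
93,0.186668591022131
94,0.203205090400911
95,0.22100171465755
96,0.240113385662206
97,0.260588848146066
98,0.282468510038475
99,0.305781981228314
100,0.330545317616759
101,0.356757995218995
102,0.384399662521812
103,0.413426748869846
104,0.443769042536948
105,0.475326393954787
106,0.507965746053772
107,0.541518742341398
108,0.575780210147894
109,0.610507855470148
110,1
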