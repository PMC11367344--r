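age	qx
0	0.000226190570082885
1	0.000228802647704751
2	0.000231675034113366
3	0.000234833669735868
4	0.000238307079847622
5	0.000242126632103101
6	0.000246326819717257
7	0.000250945572848993
8	0.000256024600996052
9	0.000261609769484972
10	0.000267751513449932
11	0.000274505293028193
12	0.000281932093874282
13	0.000290098977495767
14	0.000299079686367443
15	0.000308955309266112
16	0.000319815012811309
17	0.000331756845788456
18	0.00034488862348192
19	0.00035932889996193
20	0.000375208037051933
21	0.000392669379568167
22	0.000411870547365245
23	0.000432984855765373
24	0.000456202877083922
25	0.000481734157216973
26	0.000509809102628656
27	0.000540681054576164
28	0.000574628569065982
29	0.000611957922833972
30	0.000653005867628509
31	0.00069814265723922
32	0.000747775374089321
33	0.000802351584805128
34	0.000862363357016727
35	0.00092835167274441
36	0.00100091127711921
37	0.00108069600487959
38	0.00116842463112476
39	0.00126488729719698
40	0.0013709525673512
41	0.00148757517706788
42	0.00161580453951693
43	0.00175679408279772
44	0.00191181149721431
45	0.0020822499790013
46	0.00226964056464629
47	0.00247566565825574
48	0.00270217386333205
49	0.00295119623986173
50	0.00322496411777773
51	0.00352592860864287
52	0.00385678196879724
53	0.00422048097917083
54	0.00462027251944053
55	0.00505972152710876
56	0.00554274154528978
57	0.00607362807632017
58	0.00665709497156686
59	0.00729831410066728
60	0.00800295855554689
61	0.00877724965542748
62	0.0096280080280664
63	0.0105627090488907
64	0.011589542922582
65	0.0127174796898595
66	0.0139563394342921
67	0.0153168679482184
68	0.0168108180911593
69	0.0184510370359648
70	0.0202515595442992
71	0.0222277073403144
72	0.024396194555219
73	0.0267752390908084
74	0.0293846795909652
75	0.0322460975097087
76	0.0353829435145555
77	0.0388206671555559
78	0.0425868483529515
79	0.0467113287982561
80	0.0512263408117681
81	0.0561666305400341
82	0.0615695715947536
83	0.0674752643147807
84	0.0739266147603284
85	0.0809693863096644
86	0.0886522153128121
87	0.0970265806582853
88	0.106146715329624
89	0.116069446081813
90	0.126853945282981
91	0.138561376795655
92	0.151254415595332
93	0.164996618761638
94	0.179851623696969
95	0.195882148157705
96	0.213148766224751
97	0.231708435078789
98	0.251612749860915
99	0.272905908570758
100	0.295622376557808
101	0.319784251453381
102	0.345398345169863
103	0.372453020637708
104	0.400914847911058
105	0.430725177525438
106	0.461796768428002
107	0.494010652564629
108	0.527213466370672
109	1
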