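age,headcount
23,2.682926829268293
24,2.6158536585365852
25,2.548780487804878
26,2.481707317073171
27,2.4146341463414633
28,2.347560975609756
29,2.2804878048780486
30,2.2134146341463414
31,2.1463414634146343
32,2.0792682926829267
33,2.0121951219512195
34,1.9451219512195121
35,1.8780487804878048
36,1.8109756097560976
37,1.7439024390243902
38,1.6768292682926829
39,1.6097560975609757
40,1.5426829268292683
41,1.475609756097561
42,1.4085365853658536
43,1.3414634146341464
44,1.274390243902439
45,1.2073170731707317
46,1.1402439024390243
47,1.0731707317073171
48,1.0060975609756098
49,0.9390243902439024
50,0.8719512195121951
51,0.8048780487804879
52,0.7378048780487805
53,0.6707317073170732
54,0.6036585365853658
55,0.5365853658536586
56,0.4695121951219512
57,0.4024390243902439
58,0.3353658536585366
59,0.2682926829268293
60,0.20121951219512196
61,0.13414634146341464
62,0.06707317073170732
63,0
64,0
65,0
66,0
67,0
68,0
69,0
70,0
71,0
72,0
73,0
74,0
75,0
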