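"age","count"
40,3070.49864898059
41,3116.5561287153
42,3162.61360845001
43,3208.67108818472
44,3254.72856791943
45,3300.78604765414
46,3346.84352738885
47,3392.90100712356
48,3438.95848685827
49,3485.01596659297
50,3531.07344632768
51,3469.66347334807
52,3408.25350036846
53,3346.84352738885
54,3285.43355440924
55,3224.02358142962
56,3039.79366249079
57,2855.56374355195
58,2671.33382461312
59,2487.10390567428
60,2302.87398673545
61,2284.45099484156
62,2266.02800294768
63,2247.60501105379
64,2229.18201915991
65,2210.75902726603
66,2106.36207320069
67,2001.96511913535
68,1897.56816507001
69,1793.17121100467
70,1688.77425693933
71,1547.53131908622
72,1406.28838123311
73,1265.04544338001
74,1123.8025055269
75,982.55956767379
76,896.585605502334
77,810.611643330877
78,724.63768115942
79,638.663718987964
80,552.689756816507
81,491.279783836895
82,429.869810857283
83,368.459837877671
84,307.049864898059
85,245.639891918448
86,214.934905428642
87,184.229918938836
88,153.52493244903
89,122.819945959224
90,92.1149594694178
91,78.6047654139032
92,65.0945713583886
93,51.584377302874
94,38.0741832473594
95,24.5639891918448
96,20.2652910832719
97,15.9665929746991
98,11.6678948661263
99,7.36919675755343
100,3.07049864898059
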