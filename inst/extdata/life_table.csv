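"age","qx"
40,0.002
41,0.0021774341333968
42,0.00237060970264073
43,0.00258092324174578
44,0.00280989518112719
45,0.00305918083932676
46,0.00333058238989177
47,0.00362606188992031
48,0.0039477554644609
49,0.00429798874931044
50,0.00467929370385198
51,0.00509442691547802
52,0.0055463895279286
53,0.00603844893761314
54,0.00657416241476624
55,0.00715740282020316
56,0.00779238660359043
57,0.00848370428564087
58,0.00923635364459956
59,0.0100557758469375
60,0.0109478947834544
61,0.0119191598951652
62,0.0129765927985734
63,0.0141278380474024
64,0.015381218397758
65,0.0167457949762545
66,0.0182314327860806
67,0.0198488720245707
68,0.0216098057278625
69,0.0235269643039607
70,0.0256142075653261
71,0.0278866249263257
72,0.0303606444899078
73,0.0330541518121253
74,0.0359866192031006
75,0.039179246499192
76,0.0426551143240538
77,0.0464393509465687
78,0.0505593139419258
79,0.0550447879691369
80,0.059928200094794
81,0.0652448542197189
82,0.071033186303257
83,0.0773350422303228
84,0.0841959803299938
85,0.0916656007326669
86,0.0997979039468157
87,0.108651681247626
88,0.118290939699765
89,0.128785364886925
90,0.140210824693376
91,0.152649917779535
92,0.166192570716688
93,0.180936688097738
94,0.196988860323893
95,0.214465134184089
96,0.23349185179798
97,0.254206563987474
98,0.276759024679921
99,0.301312273531834
100,0.328043814599804
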