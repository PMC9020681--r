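"age","qx"
55,0.00313745475928007
56,0.00345547677227875
57,0.00381178004807048
58,0.0042109563083903
59,0.00465814386419061
60,0.00515909161083172
61,0.00572023024062829
62,0.00634875141509561
63,0.0070526956964081
64,0.00784105009358005
65,0.00872385613159565
66,0.00971232939833089
67,0.0108189915608757
68,0.0120578158649087
69,0.0134443871317839
70,0.0149960772398927
71,0.0167322370093923
72,0.0186744052896148
73,0.0208465358602068
74,0.0232752424801866
75,0.0259900620288753
76,0.0290237351487491
77,0.032412503085968
78,0.0361964184855719
79,0.0404196666828247
80,0.045130892478691
81,0.0503835254254187
82,0.0562360941980862
83,0.0627525176022518
84,0.0700023560739096
85,0.078061003072862
86,0.0870097904693072
87,0.0969359758110829
88,0.107932572209555
89,0.120097973534544
90,0.13353531880324
91,0.148351530374961
92,0.164655951325937
93,0.182558498970427
94,0.202167245095928
95,0.223585330759985
96,0.246907126719525
97,0.272213562681584
98,0.299566573255905
99,0.329002650108311
100,0.360525553168143
101,0.394098323619914
102,0.429634861723937
103,0.466991484962825
104,0.505959064151943
105,0.546256537845113
106,0.587526809796524
107,0.629336208928431
108,0.671178789989867
109,0.71248671524551
110,0.752647712826581
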