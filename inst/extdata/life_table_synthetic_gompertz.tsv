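age	qx
60	0.00923119696608779
61	0.0103045827373303
62	0.0115027797349108
63	0.0128403007673997
64	0.0143333461647445
65	0.016
66	0.0178604491273419
67	0.0199372276893981
68	0.0222554900554205
69	0.0248433154961814
70	0.0277320482858783
71	0.0309566773504325
72	0.0345562600605586
73	0.0385743953026754
74	0.0430597515575882
75	0.0480666563831429
76	0.0536557544407844
77	0.0598947420361738
78	0.0668591870707719
79	0.07463344433581
80	0.0833116772348776
81	0.0929989983104414
82	0.103812742388587
83	0.115883887762576
84	0.129358642628881
85	0.144400215990946
86	0.161190794480217
87	0.17993374903811
88	0.200856098186692
89	0.224211257723738
90	0.250282110147011
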