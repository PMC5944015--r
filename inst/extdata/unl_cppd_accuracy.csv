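plant_sequence,dataset,n_leaves,detected,false,accuracy
Plant_001-9,CPPD-I,116,93,1,0.79
Plant_001-9,CPPD-II,168,157,5,0.83
Plant_006-25,CPPD-I,138,136,0,0.98
Plant_006-25,CPPD-II,205,188,5,0.91
Plant_008-19,CPPD-I,142,140,0,0.98
Plant_008-19,CPPD-II,210,200,9,0.86
Plant_016-20,CPPD-I,103,86,0,0.83
Plant_016-20,CPPD-II,141,129,0,0.88
Plant_023-1,CPPD-I,113,101,0,0.89
Plant_023-1,CPPD-II,154,135,8,0.83
Plant_045-1,CPPD-I,122,120,3,0.96
Plant_045-1,CPPD-II,177,170,6,0.93
Plant_047-25,CPPD-I,148,142,2,0.94
Plant_047-25,CPPD-II,212,196,5,0.88
Plant_063-32,CPPD-I,149,138,0,0.93
Plant_063-32,CPPD-II,214,174,18,0.72
Plant_070-11,CPPD-I,125,111,0,0.89
Plant_070-11,CPPD-II,177,148,5,0.83
Plant_071-8,CPPD-I,141,131,0,0.93
Plant_071-8,CPPD-II,199,163,7,0.77
Plant_076-24,CPPD-I,135,126,2,0.92
Plant_076-24,CPPD-II,191,152,2,0.78
Plant_104-24,CPPD-I,144,140,0,0.97
Plant_104-24,CPPD-II,186,185,0,0.96
Plant_191-28,CPPD-I,137,111,0,0.96
Plant_191-28,CPPD-II,178,151,7,0.81
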