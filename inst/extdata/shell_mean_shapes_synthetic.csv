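"point","fab_x","fab_y","obt_x","obt_y"
1,1,0,0.78,0
2,0.9749,0.2548,0.7604,0.2998
3,0.901,0.4904,0.7028,0.5814
4,0.7818,0.6898,0.6098,0.8281
5,0.6235,0.8402,0.4863,1.026
6,0.4339,0.9341,0.3384,1.1653
7,0.2225,0.9696,0.1736,1.2404
8,0,0.95,0,1.25
9,-0.2225,0.8828,-0.1736,1.197
10,-0.4339,0.7777,-0.3384,1.0871
11,-0.6235,0.6452,-0.4863,0.9285
12,-0.7818,0.4948,-0.6098,0.7306
13,-0.901,0.334,-0.7028,0.5033
14,-0.9749,0.168,-0.7604,0.2565
15,-1,0,-0.78,0
16,-0.9749,-0.168,-0.7604,-0.2565
17,-0.901,-0.334,-0.7028,-0.5033
18,-0.7818,-0.4948,-0.6098,-0.7306
19,-0.6235,-0.6452,-0.4863,-0.9285
20,-0.4339,-0.7777,-0.3384,-1.0871
21,-0.2225,-0.8828,-0.1736,-1.197
22,0,-0.95,0,-1.25
23,0.2225,-0.9696,0.1736,-1.2404
24,0.4339,-0.9341,0.3384,-1.1653
25,0.6235,-0.8402,0.4863,-1.026
26,0.7818,-0.6898,0.6098,-0.8281
27,0.901,-0.4904,0.7028,-0.5814
28,0.9749,-0.2548,0.7604,-0.2998
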