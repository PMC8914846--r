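ta,vp,tmrt,v,pet
25.5902,9.1312,41.6458,0.7615,28.693891
20.5571,19.7931,50.7137,1.5703,27.946617
15.9417,19.8420,29.1851,1.8085,17.116964
39.9583,10.5226,42.5679,0.3626,39.556372
16.4791,20.7623,41.9566,0.4631,26.855677
16.2682,13.3204,44.2158,0.3777,27.079395
30.8180,21.5850,45.8675,0.4401,37.611968
27.3020,7.7561,20.6511,0.9488,21.887519
22.8075,23.0687,49.9021,1.6062,29.900582
30.0412,18.9555,16.4332,0.5075,24.619987
18.0458,12.2557,32.6745,1.9151,18.255206
28.7360,15.3636,30.3762,1.5024,27.033038
35.3413,19.1135,50.7501,1.7236,38.803668
39.9198,19.6941,58.9334,0.7370,47.255774
15.7230,21.0387,49.5630,1.6960,23.656394
20.7786,20.0522,56.2697,1.8923,29.222612
39.6846,8.2806,32.7689,0.3790,34.621151
15.9999,9.5639,34.8270,1.0471,18.550072
27.5654,20.7583,46.6229,0.8316,33.972176
22.7144,11.9536,46.9633,1.8259,26.373863
39.3589,17.2623,57.3903,1.4378,44.124242
15.1887,8.7445,36.2069,0.5949,20.204452
31.1578,15.2285,29.2715,1.1751,28.669402
34.9588,10.9008,26.1395,0.6918,29.585379
17.6041,11.8257,50.7691,0.2200,33.071390
15.6710,5.7428,40.5296,1.3490,18.669892
27.0156,22.8412,24.7212,0.5018,26.504563
30.2021,8.0629,18.7831,0.9055,23.426158
30.1738,20.8369,35.9675,0.8633,31.618804
24.3678,20.5056,28.8122,1.7306,23.974129
17.6086,7.5729,44.2818,1.1253,22.503863
22.9417,16.7718,38.0193,0.7821,26.899920
28.2513,15.6141,33.0099,0.5556,28.924926
31.4114,20.1303,27.7899,1.6611,29.160123
17.0958,21.3168,19.9144,0.3213,18.801524
36.4470,16.2075,47.6492,0.6148,39.997065
38.7096,21.9235,57.6923,1.3880,44.676245
23.6693,13.1618,46.5812,0.7728,30.135459
29.2827,5.2173,34.6087,0.4791,28.394768
15.2974,12.2229,50.1220,1.0116,24.441696
21.7393,12.8850,59.4508,1.5916,30.673388
30.4496,7.0096,52.2881,1.3509,34.149289
24.9139,15.5672,55.3034,0.9356,34.318624
24.0669,19.4356,53.1822,0.5505,35.793438
36.9108,20.1960,45.3292,0.5565,40.224291
18.1815,16.0176,21.8558,1.5880,16.475115
29.4240,10.5907,46.1710,1.0080,32.614434
20.1190,21.6288,42.0779,0.5210,28.929243
17.4276,16.6742,25.6507,0.5041,19.496562
37.6910,14.6944,52.7717,1.6364,40.563811
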