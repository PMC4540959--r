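energy_keV,mu_over_rho_cm2_g
10,3.879
10.635,3.26063
11.31,2.74105
12.028,2.30419
12.791,1.9372
13.603,1.62846
14.467,1.3688
15,1.236
15.385,1.16275
16.362,1.00238
17.401,0.864131
18.505,0.745044
19.68,0.642294
20,0.6178
20.929,0.571183
22.258,0.51354
23.671,0.461727
25.173,0.415162
26.771,0.373276
28.471,0.335605
30,0.3066
30.278,0.303736
32.2,0.2853
34.244,0.267983
36.418,0.251716
38.73,0.236436
40,0.2288
41.188,0.224502
43.803,0.215724
46.584,0.20729
49.541,0.199187
50,0.198
52.686,0.193178
56.03,0.187657
59.587,0.182292
60,0.1817
63.37,0.178176
67.392,0.17429
71.67,0.170488
76.22,0.166768
80,0.1639
81.058,0.163231
86.204,0.160133
91.676,0.157094
97.496,0.154112
100,0.1529
103.685,0.15124
110.267,0.148459
117.266,0.145729
124.711,0.143048
132.627,0.140418
141.046,0.137835
150,0.1353
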