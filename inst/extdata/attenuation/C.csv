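energy_keV,mu_over_rho_cm2_g
10,2.373
10.635,2.01456
11.31,1.7104
12.028,1.4521
12.791,1.23297
13.603,1.04678
14.467,0.888629
15,0.8071
15.385,0.765404
16.362,0.672859
17.401,0.591507
18.505,0.520049
19.68,0.457177
20,0.442
20.929,0.415816
22.258,0.382771
23.671,0.35236
25.173,0.324377
26.771,0.298606
28.471,0.274875
30,0.2562
30.278,0.254478
32.2,0.24328
34.244,0.232575
36.418,0.22234
38.73,0.212556
40,0.2076
41.188,0.204788
43.803,0.198998
46.584,0.193372
49.541,0.187906
50,0.1871
52.686,0.183634
56.03,0.179641
59.587,0.175733
60,0.1753
63.37,0.172489
67.392,0.169378
71.67,0.166322
76.22,0.163322
80,0.161
81.058,0.160418
86.204,0.157721
91.676,0.155069
97.496,0.152461
100,0.1514
103.685,0.149829
110.267,0.147194
117.266,0.144606
124.711,0.142063
132.627,0.139565
141.046,0.137111
150,0.1347
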