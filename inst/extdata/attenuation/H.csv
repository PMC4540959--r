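energy_keV,mu_over_rho_cm2_g
10,0.3854
10.635,0.38402
11.31,0.382645
12.028,0.381275
12.791,0.379911
13.603,0.378551
14.467,0.377194
15,0.3764
15.385,0.375787
16.362,0.374302
17.401,0.372823
18.505,0.371351
19.68,0.369883
20,0.3695
20.929,0.368079
22.258,0.36616
23.671,0.364252
25.173,0.362355
26.771,0.360467
28.471,0.358589
30,0.357
30.278,0.356635
32.2,0.354212
34.244,0.351804
36.418,0.349413
38.73,0.347038
40,0.3458
41.188,0.344431
43.803,0.34157
46.584,0.338733
49.541,0.33592
50,0.3355
52.686,0.332745
56.03,0.329535
59.587,0.326355
60,0.326
63.37,0.32272
67.392,0.319066
71.67,0.315453
76.22,0.311881
80,0.3091
81.058,0.308215
86.204,0.3041
91.676,0.30004
97.496,0.296035
100,0.2944
103.685,0.291658
110.267,0.287054
117.266,0.282523
124.711,0.278062
132.627,0.273673
141.046,0.269352
150,0.2651
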