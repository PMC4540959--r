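energy_keV,mu_over_rho_cm2_g
10,5.952
10.635,4.97858
11.31,4.1647
12.028,3.48373
12.791,2.9145
13.603,2.43796
14.467,2.03916
15,1.836
15.385,1.71824
16.362,1.46265
17.401,1.2451
18.505,1.06004
19.68,0.90238
20,0.8651
20.929,0.788476
22.258,0.695302
23.671,0.613159
25.173,0.540751
26.771,0.476868
28.471,0.420516
30,0.3779
30.278,0.373327
32.2,0.344198
34.244,0.317341
36.418,0.292578
38.73,0.269747
40,0.2585
41.188,0.25205
43.803,0.239003
46.584,0.226633
49.541,0.214904
50,0.2132
52.686,0.206484
56.03,0.198855
59.587,0.191507
60,0.1907
63.37,0.186122
67.392,0.181098
71.67,0.176209
76.22,0.171451
80,0.1678
81.058,0.167024
86.204,0.163437
91.676,0.159928
97.496,0.156493
100,0.1551
103.685,0.153302
110.267,0.150291
117.266,0.147339
124.711,0.144445
132.627,0.141608
141.046,0.138827
150,0.1361
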