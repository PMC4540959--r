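energy_keV,mu_over_rho_cm2_g
10,26.23
10.635,21.8838
11.31,18.2592
12.028,15.2344
12.791,12.7124
13.603,10.6065
14.467,8.84863
15,7.955
15.385,7.38887
16.362,6.1757
17.401,5.16175
18.505,4.31494
19.68,3.60654
20,3.441
20.929,3.037
22.258,2.56388
23.671,2.16456
25.173,1.82758
26.771,1.54294
28.471,1.30257
30,1.128
30.278,1.10349
32.2,0.953028
34.244,0.823083
36.418,0.710844
38.73,0.613911
40,0.5685
41.188,0.536997
43.803,0.476322
46.584,0.422502
49.541,0.374772
50,0.3681
52.686,0.339535
56.03,0.308765
59.587,0.280778
60,0.2778
63.37,0.261436
67.392,0.244159
71.67,0.228022
76.22,0.212949
80,0.2018
81.058,0.1998
86.204,0.190693
91.676,0.182003
97.496,0.173707
100,0.1704
103.685,0.167201
110.267,0.161898
117.266,0.156763
124.711,0.15179
132.627,0.146976
141.046,0.142314
150,0.1378
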