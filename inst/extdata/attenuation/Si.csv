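energy_keV,mu_over_rho_cm2_g
10,33.89
10.635,28.3003
11.31,23.6345
12.028,19.7372
12.791,16.4847
13.603,13.7665
14.467,11.4954
15,10.34
15.385,9.6025
16.362,8.02255
17.401,6.7026
18.505,5.60068
19.68,4.67926
20,4.464
20.929,3.93158
22.258,3.3096
23.671,2.78614
25.173,2.34566
26.771,1.97468
28.471,1.66228
30,1.436
30.278,1.40337
32.2,1.20385
34.244,1.03269
36.418,0.885859
38.73,0.759901
40,0.7012
41.188,0.659329
43.803,0.579246
46.584,0.50889
49.541,0.447091
50,0.4385
52.686,0.400843
56.03,0.360674
59.587,0.324524
60,0.3207
63.37,0.299262
67.392,0.276832
71.67,0.256079
76.22,0.236881
80,0.2228
81.058,0.220269
86.204,0.208788
91.676,0.197907
97.496,0.187592
100,0.1835
103.685,0.179662
110.267,0.173317
117.266,0.167197
124.711,0.161291
132.627,0.155596
141.046,0.150101
150,0.1448
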