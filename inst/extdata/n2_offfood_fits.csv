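id,label,length_min,n_step,min_step,max_step,est_xmin,n_tail,est_alpha,distance
1,,12,213,0.009,13.339,2.113,19,3.600,0.920
2,,20,331,0.003,6.660,1.320,68,3.622,0.798
3,,8,106,0.043,7.289,2.516,16,4.260,0.858
4,,10,340,0.012,2.663,1.186,30,4.988,0.915
5,,20,364,0.002,4.136,1.482,42,4.491,0.887
6,,17,219,0.007,7.156,1.283,77,3.118,0.653
7,A,18,253,0.003,5.821,0.756,105,2.581,0.589
8,,20,445,0.002,5.825,1.038,90,3.509,0.802
9,,20,349,0.005,4.406,2.012,33,4.749,0.908
10,,17,306,0.002,6.267,1.243,54,3.034,0.827
11,,20,250,0.015,8.080,1.591,50,3.574,0.804
12,,12,265,0.002,4.002,1.714,28,5.456,0.898
13,,18,231,0.004,11.206,1.816,41,3.251,0.827
14,B,20,239,0.008,12.621,1.724,53,2.987,0.782
15,,20,317,0.005,5.215,1.578,47,4.143,0.855
16,,20,351,0.002,4.052,1.124,55,3.968,0.846
17,C,20,356,0.000,4.284,0.473,175,2.352,0.511
18,,20,380,0.000,3.144,1.433,36,5.781,0.908
19,,20,345,0.000,7.446,1.789,26,4.486,0.928
20,,20,345,0.001,3.743,1.525,40,4.860,0.887
21,,20,276,0.016,10.598,1.530,75,3.502,0.732
22,,20,384,0.000,3.630,0.884,84,3.126,0.784
23,,12,199,0.004,4.091,1.231,65,3.259,0.678
24,,16,222,0.022,4.383,1.741,24,5.449,0.896
25,,20,360,0.007,3.257,1.590,26,6.126,0.931
26,,20,331,0.005,3.866,1.801,39,4.922,0.885
27,,20,319,0.001,6.337,1.671,53,3.883,0.837
28,D,20,326,0.000,5.397,0.578,108,2.366,0.672
29,E,19,265,0.004,5.314,0.953,86,2.722,0.683
30,,20,258,0.014,5.929,2.956,17,6.938,0.938
31,,20,335,0.001,4.062,1.655,41,5.875,0.881
32,,20,656,0.002,2.915,1.008,64,4.608,0.904
33,F,9,116,0.018,7.607,0.369,71,1.893,0.405
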