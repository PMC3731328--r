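Z,r,a1,b1,a2,b2,a3,b3,delta_max,delta_mean,delta_std
1,2.0,1,1,1E5,1,1E5,1,0.49407,0.30869,0.16277
2,1.994,1.07342,0.64272,0.12568,0.0845,0.14111,0.17253,2.95168,0.77506,0.97183
3,2.934,0.38714,0.09257,0.07786,0.554,0.01882,0.00128,2.80411,0.82839,0.47785
4,2.998,0.28152,0.01825,0.04686,0.1465,0.01342,5.8E-4,2.95438,1.19439,0.74471
5,2.9952,0.2303,0.00808,0.03316,0.06074,0.01083,3.69E-4,2.83182,1.15413,0.76625
6,2.87,0.18732,0.00503,0.02471,0.03378,0.01421,5.79E-4,2.91821,1.27202,0.93683
7,3.0808,0.13286,0.2496,0.02926,0.00127,0.00181,7.6E-4,2.57067,1.26022,0.67697
8,2.5968,0.0939,0.13992,0.02472,0.00135,0.00813,0.01953,2.52609,0.96599,0.93648
9,2.676,0.08332,0.09631,0.02226,0.00101,0.00534,0.00698,2.76167,1.30524,0.83583
10,2.6768,0.07474,0.0664,0.02016,8.15E-4,0.004,0.00361,2.97721,1.32855,0.94562
11,2.4892,0.0539,0.0382,0.01797,7.56E-4,0.00855,0.11457,2.9295,1.10247,0.95764
12,2.573,0.05214,0.02571,0.01662,5.95E-4,0.00493,0.03657,3.02582,1.03358,1.00879
13,2.5948,0.04874,0.01839,0.01539,4.96E-4,0.00361,0.02043,3.19991,0.96117,1.05342
14,2.7396,0.04866,0.01224,0.01441,3.82E-4,0.00192,0.00521,3.36012,0.94039,1.03047
15,2.8128,0.04704,0.00832,0.01354,3.14E-4,0.00121,0.00187,3.62753,0.88091,1.05631
16,2.9188,0.0459,0.00561,0.01276,2.54E-4,6.6E-4,5.16E-4,3.6664,0.84291,1.03753
17,3.0348,0.04484,0.00368,0.0121,2.06E-4,3.104E-4,1.059E-4,3.85843,0.84603,1.05476
18,3.1704,0.0439,0.00232,0.01151,1.66E-4,1.073E-4,1.188E-5,3.97441,0.86797,1.0771
19,3.1948,0.0416,0.00176,0.01105,1.48E-4,7.923E-5,6.49E-6,3.85914,1.55547,1.10554
20,3.1412,0.03902,0.00155,0.01046,1.38E-4,1.059E-4,1.21E-5,3.9819,1.79997,0.95174
21,2.5908,0.03036,0.00331,0.00964,1.83E-4,0.00112,0.0016,3.95707,1.98217,1.083
22,2.5368,0.02814,0.00307,0.00923,1.73E-4,0.00116,0.00172,3.98871,2.09126,1.16429
23,2.7128,0.02944,0.00212,0.00877,1.36E-4,6.294E-4,4.761E-4,4.44428,1.99762,1.22413
24,2.7208,0.02866,0.00167,0.00854,1.26E-4,5.428E-4,3.244E-4,4.23959,1.68691,1.0518
25,2.536,0.02488,0.00207,0.00813,1.32E-4,8.906E-4,9.251E-4,4.80743,2.1238,1.15358
26,2.58,0.02458,0.00171,0.00785,1.18E-4,7.26E-4,5.92E-4,4.83153,2.05015,1.15511
27,2.632,0.02438,0.00137,0.00763,1.05E-4,5.73E-4,3.55E-4,4.81653,2.05999,1.19439
28,2.648,0.02378,0.00123,0.00727,9.46E-5,5.05E-4,2.69E-4,4.85159,1.98741,1.23426
29,2.648,0.02328,0.00102,0.00712,8.91E-5,4.61E-4,2.12E-4,4.23183,1.73644,1.1373
30,2.78,0.02398,7.35E-4,0.00677,7.09E-5,2.304E-4,5.28E-5,4.96515,2.22336,1.32416
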