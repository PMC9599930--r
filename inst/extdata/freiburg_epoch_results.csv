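patient,sensitivity,specificity,accuracy,g_mean
1,100,99.49,99.49,99.74
2,100,96.98,96.98,98.47
3,100,97.50,97.50,98.74
4,92.35,99.03,99.01,95.63
5,100,99.89,99.89,99.94
6,100,99.08,99.08,99.53
7,100,99.83,99.83,99.91
8,100,97.01,97.01,98.49
9,98.67,96.20,96.20,97.42
10,91.52,95.95,95.49,93.70
11,100,99.96,99.96,99.97
12,100,99.98,99.98,99.99
13,100,99.85,99.85,99.92
14,98.01,98.31,98.26,98.15
15,100,98.47,98.47,99.23
16,100,98.91,98.91,99.45
17,100,99.55,99.55,99.74
18,52,96.78,96.74,70.94
19,71.21,99.97,99.97,84.37
20,100,98.79,98.79,99.39
21,95.40,98.24,97.98,96.80
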