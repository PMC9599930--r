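patient,n_reference,n_detected,event_sensitivity,fdr_per_hour
1,2,2,100,0.35
2,1,1,100,0.70
3,3,3,100,0.89
4,4,3,75,0.15
5,3,3,100,0.03
6,2,2,100,0.20
7,2,2,100,0.07
8,1,1,100,0.29
9,3,3,100,0.80
10,3,2,67,0.87
11,2,2,100,0.06
12,3,3,100,0.09
13,1,1,100,0.07
14,3,3,100,0.43
15,2,2,100,0.12
16,3,3,100,0.26
17,4,4,100,0.10
18,3,2,67,1.41
19,2,2,100,0.03
20,3,3,100,0.16
21,4,4,100,0.43
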