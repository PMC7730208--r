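subject,MA_zscore,MA_tvalue,MA_allchannels,LMI_zscore,LMI_tvalue,LMI_allchannels,RMI_zscore,RMI_tvalue,RMI_allchannels
1,75,85,90,90,70,55,90,70,75
2,90,70,80,85,80,90,85,65,75
3,80,70,70,95,75,65,90,80,75
4,95,80,80,85,70,75,85,80,65
5,90,65,55,90,55,80,85,75,65
6,90,45,55,95,80,85,90,60,65
7,90,70,80,80,65,65,90,55,85
8,90,60,90,90,80,85,85,85,85
9,90,80,60,75,65,70,100,90,85
10,85,80,85,80,70,75,85,80,70
11,95,90,85,85,70,70,95,70,70
12,90,75,75,95,80,80,75,65,65
13,95,45,70,90,70,70,90,90,80
14,90,70,70,95,85,90,95,65,65
15,95,70,75,85,85,85,90,75,90
16,75,75,70,90,80,75,90,60,80
17,85,80,80,95,80,85,95,80,85
18,85,90,90,90,70,85,90,90,90
19,85,80,85,70,85,85,80,85,80
20,95,95,85,95,50,80,95,60,60
21,75,80,80,85,75,80,85,60,90
22,85,75,85,80,60,70,95,80,75
23,80,75,80,95,80,80,80,65,70
24,95,60,80,80,70,85,90,35,75
25,100,90,80,95,85,90,75,45,50
26,90,85,90,80,80,70,95,70,75
27,80,65,75,85,75,65,95,85,85
28,100,60,70,95,85,85,90,75,90
29,85,80,80,80,85,80,80,45,55
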