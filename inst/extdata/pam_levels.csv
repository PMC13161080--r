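pam_score,level
1,2
2,2
3,2
4,2
5,3
6,3
7,3
8,3
9,1
10,1
11,1
12,1
13,4
14,4
15,4
16,4
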