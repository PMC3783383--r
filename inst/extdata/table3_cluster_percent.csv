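taxa_count,n_characters,r1,r2,r3,r4,r5,r6,r7,r8,r9,r10,printed_average
5,5,100,60,60,60,60,100,60,60,100,100,76
5,7,100,100,60,80,60,100,80,100,80,100,86
6,5,33,100,100,100,67,100,100,100,83,100,88
6,7,50,100,100,100,67,100,100,100,83,100,90
7,5,100,86,100,71,100,100,100,57,57,86,86
7,7,100,86,100,86,100,100,100,71,71,86,90
8,5,75,75,75,75,88,100,88,100,75,75,83
8,7,75,75,88,88,88,100,63,88,50,100,81
9,5,78,56,78,78,56,78,100,67,89,78,76
9,7,78,67,100,78,67,78,100,89,89,89,83
10,5,90,90,60,60,70,60,90,60,50,80,71
10,7,90,90,100,60,100,100,90,60,60,100,85
11,5,64,55,64,55,64,100,55,55,64,64,64
11,7,45,55,64,36,64,82,55,55,45,55,55
12,5,67,75,67,50,75,67,92,67,83,75,72
12,7,67,58,58,58,67,83,92,83,75,58,70
13,5,62,62,69,62,62,62,62,62,69,69,64
13,7,62,62,62,46,62,85,62,62,69,69,64
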