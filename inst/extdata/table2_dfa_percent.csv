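taxa_count,n_characters,r1,r2,r3,r4,r5,r6,r7,r8,r9,r10,printed_average
5,7,100,100,100,100,100,100,100,100,100,100,100
5,5,100,100,100,100,100,100,100,100,100,100,100
6,7,100,100,100,100,100,100,100,100,100,100,100
6,5,100,100,100,100,100,100,100,100,100,100,100
7,7,100,100,100,97.8,100,100,100,100,100,100,100
7,5,100,100,100,91.1,100,100,100,100,100,100,99
8,7,100,97.8,100,100,100,100,100,100,100,100,100
8,5,100,91.8,100,100,100,100,100,100,100,100,99
9,7,94.5,100,100,100,98.2,94.7,100,100,100,100,99
9,5,92.7,100,100,100,92.7,92.9,100,100,100,100,98
10,7,100,100,100,100,100,100,100,100,100,100,100
10,5,100,100,100,93.1,100,100,100,93.3,100,100,99
11,7,100,98.4,100,98.4,98.3,100,96.8,98.4,98.5,98.4,99
11,5,100,93.7,100,93.7,93.5,100,93.7,93.7,89.5,93.7,95
12,7,100,95.9,95.8,95.7,100,98.6,100,91.1,100,95.4,97
12,5,100,94.6,94.4,94.4,100,94.6,100,91.2,100,93.8,96
13,7,96.2,96.2,94.9,96.2,96.1,98.7,96.1,96.1,100,100,97
13,5,94.9,94.9,92.4,95,94.9,95,94.8,94.8,100,100,96
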