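t,r,g,b
0.00,0.2422,0.1504,0.6603
0.10,0.2810,0.3228,0.9579
0.20,0.2081,0.4667,0.9904
0.30,0.1156,0.5793,0.9155
0.40,0.0770,0.6618,0.8387
0.50,0.0914,0.7253,0.6923
0.60,0.2941,0.7648,0.4755
0.70,0.5761,0.7686,0.2905
0.80,0.8201,0.7327,0.2118
0.90,0.9892,0.7554,0.1459
1.00,0.9769,0.9839,0.0805
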