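percent_water,density_g_per_l
0,780.8
1,783.0
2,785.1
3,787.3
4,789.5
5,791.6
100,997.1
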