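"concentration_uM","luminescence","replicate"
15,95.12,1
15,96.4,2
15,103.36,3
7.5,82.05,1
7.5,82.24,2
7.5,87.43,3
3.75,63.21,1
3.75,58.93,2
3.75,60.36,3
1.875,41.11,1
1.875,43.91,2
1.875,42.46,3
0.9375,25.76,1
0.9375,25.46,2
0.9375,24.79,3
0.46875,15.19,1
0.46875,14.46,2
0.46875,13.06,3
0.234375,7.74,1
0.234375,7.39,2
0.234375,7.21,3
0.1171875,3.85,1
0.1171875,3.73,2
0.1171875,3.77,3
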