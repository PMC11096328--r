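>M001
1.000000	0.000000	0.000000	0.000000
1.000000	0.000000	0.000000	0.000000
1.000000	0.000000	0.000000	0.000000
1.000000	0.000000	0.000000	0.000000
>M002
0.500000	0.500000	0.000000	0.000000
0.500000	0.500000	0.000000	0.000000
0.500000	0.500000	0.000000	0.000000
0.500000	0.500000	0.000000	0.000000
>M003
0.100000	0.700000	0.100000	0.100000
0.100000	0.700000	0.100000	0.100000
0.100000	0.700000	0.100000	0.100000
0.100000	0.700000	0.100000	0.100000
0.100000	0.700000	0.100000	0.100000
>M005
0.000000	0.000000	0.000000	1.000000
0.000000	0.000000	0.000000	1.000000
0.000000	0.000000	0.000000	1.000000
0.000000	0.000000	0.000000	1.000000
0.000000	0.000000	0.000000	1.000000
>M006
0.000000	0.000000	0.000000	1.000000
0.000000	0.000000	0.000000	1.000000
0.000000	0.000000	0.000000	1.000000
0.000000	0.000000	0.000000	1.000000
0.000000	0.000000	0.000000	1.000000
>M007
0.250000	0.250000	0.250000	0.250000
1.000000	0.000000	0.000000	0.000000
0.000000	1.000000	0.000000	0.000000
0.000000	0.000000	1.000000	0.000000
0.250000	0.250000	0.250000	0.250000
>M008
0.300000	0.300000	0.200000	0.200000
0.250000	0.250000	0.250000	0.250000
0.250000	0.250000	0.250000	0.250000
0.250000	0.250000	0.250000	0.250000
0.250000	0.250000	0.250000	0.250000
0.250000	0.250000	0.250000	0.250000
0.300000	0.300000	0.200000	0.200000
>M009
0.700000	0.100000	0.100000	0.100000
0.700000	0.100000	0.100000	0.100000
0.700000	0.100000	0.100000	0.100000
0.700000	0.100000	0.100000	0.100000
0.700000	0.100000	0.100000	0.100000
>M010
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.050000	0.850000	0.050000
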