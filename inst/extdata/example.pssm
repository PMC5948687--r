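
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M    -2  -2  -3  -4  -2  -1  -3  -4  -3   1   2  -2   8   0  -4  -3  -2  -2  -2   0
    2 K    -1   2   0  -1  -4   1   1  -2  -1  -3  -3   5  -2  -4  -1  -1  -1  -4  -2  -3
    3 V     0  -3  -3  -4  -1  -3  -3  -4  -4   2   0  -3   1  -1  -3  -2   0  -3  -1   4
    4 A     4  -2  -2  -2  -1  -1  -1   0  -2  -2  -2  -1  -1  -3  -1   1   0  -3  -2   0

                      K         0.0410
Lambda                0.2670
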