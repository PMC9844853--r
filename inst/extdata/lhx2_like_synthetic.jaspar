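>LHX2_like_synthetic homeodomain-type TAATTA-core motif (synthetic counts, not a database matrix)
A [  14  90  95   2   4  85  30 ]
C [   8   4   2   3   4   5  25 ]
G [   8   3   2   3   4   5  25 ]
T [  70   3   1  92  88   5  20 ]
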