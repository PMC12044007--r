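>SYN_ETS SYN_ETS
A [  5  8  3  2 90 95  5  4 ]
C [ 60 62  5  5  3  1  5  6 ]
G [ 20 20 85 88  5  2 80 10 ]
T [ 15 10  7  5  2  2 10 80 ]
>SYN_AP1 SYN_AP1
A [  4  2 90  2  5  2 85 ]
C [  6  3  3 88  3 88  5 ]
G [  5 90  4  5  2  4  5 ]
T [ 85  5  3  5 90  6  5 ]
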