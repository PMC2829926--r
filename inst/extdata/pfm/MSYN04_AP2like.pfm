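>MSYN04_AP2like synthetic AP2-alpha-like site
A [  1  1  2  5  5  1  1  1 ]
C [ 16  16 14  5  5  1 14 16 ]
G [  2  2  2  5  5 17  3  2 ]
T [  1  1  2  5  5  1  2  1 ]
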