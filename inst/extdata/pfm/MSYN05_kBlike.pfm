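>MSYN05_kBlike synthetic rel-like site
A [  1  1  1 16  1  1  1  1  2  1 ]
C [  1  1  1  1 15  1  1  1  2 16 ]
G [ 17 17 17  2  2  1  1  2 14  2 ]
T [  1  1  1  1  2 17 17 16  2  1 ]
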