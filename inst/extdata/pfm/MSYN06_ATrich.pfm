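>MSYN06_ATrich synthetic MEF2-like AT-rich site
A [  2 16 17 17 17 17  2  1 ]
C [  1  1  1  1  1  1  1  2 ]
G [  1  2  1  1  1  1  2 16 ]
T [ 16  1  1  1  1  1 15  1 ]
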