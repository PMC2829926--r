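>MSYN03_Ebox synthetic ARNT-like E box
A [  1  2 17  1  1  2 ]
C [ 16  1  1 17  1  1 ]
G [  2  1  1  1 17  1 ]
T [  1 16  1  1  1 16 ]
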