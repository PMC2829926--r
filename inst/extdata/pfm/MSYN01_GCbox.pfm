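>MSYN01_GCbox synthetic SP1-like GC box
A [  1  1  1  1  2  1  1  1  1 ]
C [  1  1  1  1 15  1  1  1  1 ]
G [ 17 17 17 17  2 17 17 17 17 ]
T [  1  1  1  1  1  1  1  1  1 ]
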