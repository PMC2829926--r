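>MSYN08_GClong synthetic high-information GC-rich site
A [  1  1  1  1  1 97  1  1  1  2  1 ]
C [ 97 97  1  1 96  1  1 97  1  1 97 ]
G [  1  1 97 97  1  1 97  1  2 96  1 ]
T [  1  1  1  1  2  1  1  1 96  1  1 ]
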