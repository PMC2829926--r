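>MSYN02_FKHlike synthetic forkhead-like site
A [  1  1  1  2  1  1 16  3 ]
C [  1  1  1  1  1  1  1 14 ]
G [  1  2  1  1  1  1  2  2 ]
T [ 17 16 17 16 17 17  1  1 ]
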