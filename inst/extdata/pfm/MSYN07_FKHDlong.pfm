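>MSYN07_FKHDlong synthetic high-information forkhead-domain site
A [  1  1  1  2 97  1 97 97  1  2 97  1 ]
C [  1  1  1  1  1  1  1  1  1 96  1  2 ]
G [ 97  1  1  1  1  1  1  1  1  1  1 96 ]
T [  1 97 97 96  1 97  1  1 97  1  1  1 ]
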