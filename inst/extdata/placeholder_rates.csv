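igs,tag,alpha,beta
A,A,0,0
A,C,0,0
A,G,0,0
A,U,0.006,6e-04
C,A,0,0
C,C,0,0
C,G,0.02,0.002
C,U,0,0
G,A,0,0
G,C,0.02,0.002
G,G,0,0
G,U,0,0
U,A,0.006,6e-04
U,C,0,0
U,G,0,0
U,U,0,0
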