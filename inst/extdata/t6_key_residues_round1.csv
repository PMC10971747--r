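chain,position
H,52
H,53
H,57
H,58
H,59
H,99
H,102
H,105
L,27
L,30
L,31
L,32
L,33
L,49
L,50
L,90
L,91
L,92
L,93
L,97
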