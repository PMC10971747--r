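chain,position
H,33
H,52
H,57
H,59
H,62
H,99
H,102
H,103
L,29
L,50
L,90
L,91
L,92
L,93
L,95
L,97
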