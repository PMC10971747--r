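chain,position,wt,mutated_to,effect,cdr
L,27,L,A,hit,L-CDR1
L,30,K,A,hit,L-CDR1
L,31,Y,A,hit,L-CDR1
L,32,A,G,hit,L-CDR1
L,50,D,A,hit,L-CDR2
L,90,W,A,hit,L-CDR3
L,97,L,A,hit,L-CDR3
H,52,S,A,hit,H-CDR2
H,57,S,A,hit,H-CDR2
H,59,Y,A,hit,H-CDR2
H,99,D,A,hit,H-CDR3
H,102,W,A,hit,H-CDR3
H,105,F,A,hit,H-CDR3
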