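label,ic50
H62Y,0.9479
H62F,0.8978
L95Q,0.6455
L95D,0.4777
L95Y,1.696
AMG157,1.54
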