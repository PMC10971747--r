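label,ic50
L49Y,0.6921
AMG157,0.5771
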